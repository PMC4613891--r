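<?xml version="1.0" encoding="UTF-8"?>
<ParameterSet Name="synthetic_organic_bonds" Kappa="0.42" Provenance="Synthetic bond-order (multiplicity) granularity set for small organic molecules; requires inputs with bond information (MOL/SDF/MOL2). Values chosen once in published-like ranges; for testing and demonstration only.">
  <Element Symbol="H"><Bond Type="1" A="2.55" B="10.0"/></Element>
  <Element Symbol="C">
    <Bond Type="1" A="4.05" B="8.1"/>
    <Bond Type="2" A="4.35" B="8.6"/>
    <Bond Type="3" A="4.60" B="9.0"/>
  </Element>
  <Element Symbol="N">
    <Bond Type="1" A="5.15" B="9.0"/>
    <Bond Type="2" A="5.45" B="9.4"/>
    <Bond Type="3" A="5.70" B="9.8"/>
  </Element>
  <Element Symbol="O">
    <Bond Type="1" A="6.15" B="9.6"/>
    <Bond Type="2" A="6.45" B="10.1"/>
  </Element>
  <Element Symbol="S">
    <Bond Type="1" A="4.25" B="7.0"/>
    <Bond Type="2" A="4.50" B="7.4"/>
  </Element>
</ParameterSet>
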