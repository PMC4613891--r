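<?xml version="1.0" encoding="UTF-8"?>
<ParameterSet Name="synthetic_organic_elem" Kappa="0.48" Provenance="Synthetic element-granularity set for small organic molecules (H,C,N,O,S,P; deliberately halogen-free). Values chosen once in published-like ranges; for testing and demonstration only.">
  <Element Symbol="H"><Parameters A="2.5" B="10.2"/></Element>
  <Element Symbol="C"><Parameters A="4.1" B="8.3"/></Element>
  <Element Symbol="N"><Parameters A="5.2" B="9.1"/></Element>
  <Element Symbol="O"><Parameters A="6.2" B="9.8"/></Element>
  <Element Symbol="S"><Parameters A="4.3" B="7.1"/></Element>
  <Element Symbol="P"><Parameters A="3.9" B="6.6"/></Element>
</ParameterSet>
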