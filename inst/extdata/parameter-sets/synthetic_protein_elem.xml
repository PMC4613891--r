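<?xml version="1.0" encoding="UTF-8"?>
<ParameterSet Name="synthetic_protein_elem" Kappa="0.44" Provenance="Synthetic element-granularity set for protein-like systems (H,C,N,O,S). A/B values chosen once in the ranges typical of published protein-applicable EEM sets, with Pauling electronegativity ordering; intended for testing and demonstration, not fitted to any QM reference.">
  <Element Symbol="H"><Parameters A="2.6" B="9.9"/></Element>
  <Element Symbol="C"><Parameters A="4.2" B="8.0"/></Element>
  <Element Symbol="N"><Parameters A="5.4" B="8.9"/></Element>
  <Element Symbol="O"><Parameters A="6.4" B="9.5"/></Element>
  <Element Symbol="S"><Parameters A="4.4" B="6.9"/></Element>
</ParameterSet>
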