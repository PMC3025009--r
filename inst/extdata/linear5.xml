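<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="linear5_sbml" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="B" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="C" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="D" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="lb_uptake" value="-10" constant="true"/>
      <parameter id="ub_ten" value="10" constant="true"/>
      <parameter id="ub_hundred" value="100" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_uptake" fbc:upperFluxBound="ub_hundred">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R1" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="BIOMASS" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_hundred">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_D" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_hundred">
        <listOfReactants>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
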