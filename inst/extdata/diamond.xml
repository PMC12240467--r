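<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="diamond_toy" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="B_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="C_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="A_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="true" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="ten" value="10" constant="true"/>
      <parameter id="big" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R_up" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_a1" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="gp_g1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_a2" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="gp_g2"/>
            <fbc:geneProductRef fbc:geneProduct="gp_g3"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_b" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="gp_g4"/>
            <fbc:geneProductRef fbc:geneProduct="gp_g5"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_bio" reversible="false" fast="false" fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="C_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_bio" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="gp_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="gp_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="gp_g3" fbc:label="g3"/>
      <fbc:geneProduct fbc:id="gp_g4" fbc:label="g4"/>
      <fbc:geneProduct fbc:id="gp_g5" fbc:label="g5"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>
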