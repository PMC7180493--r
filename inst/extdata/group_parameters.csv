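group,dtbm_k,dtm,dpm,dvm_cm3_mol
CH3,22.395,0.026033,0.287630,66.746
CH2,22.698,0.015200,0.206105,57.109
CH,21.842,-0.000565,0.085180,45.720
C,18.851,-0.018654,0.048162,22.091
OH,87.908,0.060416,0.062057,30.418
OH(phenol),79.134,0.031480,-0.004689,-17.274
O,20.504,0.001053,0.043617,15.634
C=O,90.202,0.015012,0.134279,69.901
COOH,167.693,0.082877,0.433805,88.656
COO,83.980,0.019191,0.064373,84.485
NH2,66.466,0.025134,0.113088,49.050
N+,35.980,-0.014120,0.080885,27.432
Cl,15.687,0.029231,0.247962,61.412
SO3H,218.658,0.044050,0.045417,185.862
CH2(ring),17.930,0.004133,0.148900,31.453
CH(ring),24.189,-0.001443,0.137088,34.903
C(ring),33.728,-0.020658,0.012643,21.007
=CH(ring),27.246,0.012837,0.196091,42.533
=C(ring),30.552,0.004618,0.104588,31.271
O(ring),15.316,0.012761,0.050086,-4.257
NH(ring),63.497,0.029548,-0.013855,83.652
N(ring),52.006,-0.000358,0.016950,42.855
N+(ring),74.456,-0.001658,0.017850,27.685
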