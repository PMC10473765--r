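region	hemisphere	compartment	human_labels	mouse_labels	human_beta	mouse_beta	human_sig	mouse_sig	expression_available
Agranular insula	left	cortical	AVI;AAIC;MI	Agranular insular area	0.200	-0.558	TRUE	TRUE	TRUE
Agranular insula	right	cortical	AVI;AAIC;MI	Agranular insular area	0.164	-0.522	TRUE	TRUE	TRUE
Amygdala	left	non_cortical	Amygdala	Cortical subplate	0.305	0.163	TRUE	TRUE	TRUE
Amygdala	right	non_cortical	Amygdala	Cortical subplate	0.201	0.151	TRUE	TRUE	TRUE
Anterior cingulate area	left	cortical	A24pr;a24;p24pr;p24;24dd;24dv;p32pr;d32;a32pr;p32;s32	Anterior cingulate area	-0.102	-0.198	TRUE	FALSE	TRUE
Anterior cingulate area	right	cortical	A24pr;a24;p24pr;p24;24dd;24dv;p32pr;d32;a32pr;p32;s32	Anterior cingulate area	-0.113	-0.267	TRUE	TRUE	TRUE
Bed nucleus of stria terminalis	left	non_cortical	Bed nucleus of stria terminalis	Bed nucleus of stria terminalis	0.466	0.918	TRUE	TRUE	TRUE
Bed nucleus of stria terminalis	right	non_cortical	Bed nucleus of stria terminalis	Bed nucleus of stria terminalis	0.360	0.971	TRUE	TRUE	TRUE
Caudoputamen	left	non_cortical	Caudate;Putamen	Caudoputamen	0.093	-0.224	FALSE	TRUE	TRUE
Caudoputamen	right	non_cortical	Caudate;Putamen	Caudoputamen	0.059	-0.188	FALSE	TRUE	TRUE
Cerebellar cortex	left	non_cortical	Cerebellar cortex	Cerebellar cortex	0.430	-0.268	TRUE	TRUE	TRUE
Cerebellar cortex	right	non_cortical	Cerebellar cortex	Cerebellar cortex	0.478	-0.250	TRUE	TRUE	TRUE
Dentate gyrus, molecular layer	left	non_cortical	Dentate gyrus, molecular layer	Dentate gyrus, molecular layer	-0.029	0.247	FALSE	TRUE	TRUE
Dentate gyrus, molecular layer	right	non_cortical	Dentate gyrus, molecular layer	Dentate gyrus, molecular layer	0.041	0.232	FALSE	TRUE	TRUE
CA1	left	non_cortical	CA1	CA1	0.151	0.385	TRUE	TRUE	TRUE
CA1	right	non_cortical	CA1	CA1	0.109	0.377	FALSE	TRUE	TRUE
CA3	left	non_cortical	CA3	CA3	0.004	0.307	FALSE	TRUE	TRUE
CA3	right	non_cortical	CA3	CA3	0.004	0.411	FALSE	TRUE	TRUE
Entorhinal cortex	left	cortical	EC	Entorhinal area	0.470	-0.090	TRUE	FALSE	TRUE
Entorhinal cortex	right	cortical	EC	Entorhinal area	0.567	-0.138	TRUE	FALSE	TRUE
Globus pallidus	left	non_cortical	Globus Pallidus	Pallidum	0.154	0.112	TRUE	TRUE	TRUE
Globus pallidus	right	non_cortical	Globus Pallidus	Pallidum	0.138	0.180	TRUE	TRUE	TRUE
Hippocampus	left	non_cortical	Hippocampus	Hippocampal region	0.120	0.353	TRUE	TRUE	TRUE
Hippocampus	right	non_cortical	Hippocampus	Hippocampal region	0.129	0.379	TRUE	TRUE	TRUE
Hypothalamus	left	non_cortical	Hypothalamus	Hypothalamus	0.631	0.185	TRUE	TRUE	TRUE
Hypothalamus	right	non_cortical	Hypothalamus	Hypothalamus	0.617	0.109	TRUE	TRUE	TRUE
Medial amygdalar nucleus	left	non_cortical	Medial amygdalar nucleus	Medial amygdalar nucleus	0.253	0.906	TRUE	TRUE	FALSE
Medial amygdalar nucleus	right	non_cortical	Medial amygdalar nucleus	Medial amygdalar nucleus	0.183	1.034	TRUE	TRUE	FALSE
Medial preoptic area	left	non_cortical	Medial preoptic area	Medial preoptic area	0.636	0.435	TRUE	TRUE	FALSE
Medial preoptic area	right	non_cortical	Medial preoptic area	Medial preoptic area	0.680	0.367	TRUE	TRUE	FALSE
Nucleus accumbens	left	non_cortical	Nucleus accumbens	Striatum ventral region	-0.311	-0.005	TRUE	FALSE	TRUE
Nucleus accumbens	right	non_cortical	Nucleus accumbens	Striatum ventral region	-0.249	0.032	TRUE	FALSE	TRUE
Perirhinal area	left	cortical	PeEc;TF;PHA2;PHA3	Perirhinal area	0.033	-0.120	FALSE	FALSE	TRUE
Perirhinal area	right	cortical	PeEc;TF;PHA2;PHA3	Perirhinal area	0.086	-0.108	FALSE	FALSE	TRUE
Piriform cortex	left	cortical	Pir	Piriform cortex	0.460	-0.131	FALSE	FALSE	TRUE
Piriform cortex	right	cortical	Pir	Piriform cortex	0.756	-0.151	TRUE	FALSE	TRUE
Posterior parietal association areas	left	cortical	5m;5mv;5L	Posterior parietal association areas	-0.254	0.016	TRUE	FALSE	TRUE
Posterior parietal association areas	right	cortical	5m;5mv;5L	Posterior parietal association areas	-0.263	0.039	TRUE	FALSE	TRUE
Primary auditory area	left	cortical	A1	Primary auditory area	-0.163	-0.256	FALSE	TRUE	TRUE
Primary auditory area	right	cortical	A1	Primary auditory area	-0.182	-0.209	TRUE	TRUE	TRUE
Primary motor area	left	cortical	4	Primary motor area	-0.124	-0.329	FALSE	TRUE	TRUE
Primary motor area	right	cortical	4	Primary motor area	-0.081	-0.357	FALSE	TRUE	TRUE
Primary somatosensory area	left	cortical	1;2;3a;3b	Primary somatosensory area	-0.237	-0.419	TRUE	TRUE	TRUE
Primary somatosensory area	right	cortical	1;2;3a;3b	Primary somatosensory area	-0.219	-0.241	TRUE	TRUE	TRUE
Primary visual area	left	cortical	V1	Primary visual area	0.175	0.029	TRUE	FALSE	TRUE
Primary visual area	right	cortical	V1	Primary visual area	0.199	-0.102	TRUE	FALSE	TRUE
Retrosplenial area	left	cortical	RSC	Retrosplenial area	0.198	0.004	TRUE	FALSE	TRUE
Retrosplenial area	right	cortical	RSC	Retrosplenial area	0.182	0.035	TRUE	FALSE	TRUE
Subiculum	left	non_cortical	PreS	Subiculum	0.182	0.317	TRUE	TRUE	TRUE
Subiculum	right	non_cortical	PreS	Subiculum	-0.031	0.338	FALSE	TRUE	TRUE
Temporal association areas	left	cortical	FFC;PIT;TE1a;TE1p;TE2a;TF;STV;STSvp;STSva	Temporal association areas	0.057	0.085	FALSE	FALSE	TRUE
Temporal association areas	right	cortical	FFC;PIT;TE1a;TE1p;TE2a;TF;STV;STSvp;STSva	Temporal association areas	0.042	-0.004	FALSE	FALSE	TRUE
Thalamus	left	non_cortical	Thalamus	Thalamus	-0.028	-0.098	FALSE	FALSE	TRUE
Thalamus	right	non_cortical	Thalamus	Thalamus	-0.060	-0.139	FALSE	TRUE	TRUE
Ventral orbital area	left	cortical	10r;10v	Ventral orbital area	0.083	-0.209	FALSE	TRUE	TRUE
Ventral orbital area	right	cortical	10r;10v	Ventral orbital area	-0.046	-0.171	FALSE	FALSE	TRUE
Brain stem	midline	non_cortical	Brainstem	Midbrain;Hindbrain	0.349	0.200	TRUE	TRUE	TRUE
Medulla	midline	non_cortical	Medulla	Medulla	0.385	0.204	TRUE	TRUE	TRUE
Midbrain	midline	non_cortical	Midbrain	Midbrain	0.423	0.191	TRUE	TRUE	TRUE
Pons	midline	non_cortical	Pons	Pons	0.279	0.065	TRUE	FALSE	TRUE
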