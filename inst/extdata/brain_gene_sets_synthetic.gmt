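nucleic_set_1	nucleic function brain gene set (synthetic)	gene00971	gene00155	gene00405	gene00667	gene00050	gene00075	gene00841	gene00549	gene00097	gene00375	gene00597	gene00060	gene00932	gene00520	gene00220	gene00039	gene00089	gene00445	gene00429	gene00072
nucleic_set_2	nucleic function brain gene set (synthetic)	gene00093	gene00565	gene00435	gene00061	gene00847	gene00580	gene00127	gene00971	gene00229	gene00646	gene00643	gene00597	gene00064	gene00591	gene00600	gene00407	gene00051
nucleic_set_3	nucleic function brain gene set (synthetic)	gene00048	gene00571	gene00880	gene00137	gene00297	gene00430	gene00148	gene00554	gene00121	gene00585	gene00316	gene00574	gene00836	gene00699	gene00186	gene00106	gene00596
cellular_set_1	cellular function brain gene set (synthetic)	gene00382	gene00100	gene00561	gene00730	gene00065	gene00578	gene00062	gene00634	gene00211	gene00509	gene00697	gene00545	gene00438	gene00796	gene00322	gene00477
cellular_set_2	cellular function brain gene set (synthetic)	gene00371	gene00307	gene00255	gene00814	gene00185	gene00716	gene00799	gene00250	gene00084	gene00589	gene00308	gene00538	gene00507	gene00897	gene00352	gene00747	gene00460	gene00295	gene00624	gene00075	gene00121	gene00525	gene00429	gene00169
cellular_set_3	cellular function brain gene set (synthetic)	gene00156	gene00956	gene00501	gene00432	gene00041	gene00986	gene00685	gene00080	gene00783	gene00572	gene00587	gene00809	gene00897	gene00838	gene00322	gene00349	gene00712	gene00359	gene00609	gene00509
signaling_set_1	signaling function brain gene set (synthetic)	gene00071	gene00861	gene00096	gene00968	gene00277	gene00486	gene00714	gene00681	gene00067	gene00063	gene00749	gene00719	gene00318	gene00663	gene00592	gene00698	gene00842	gene00457	gene00292	gene00734	gene00396	gene00909	gene00685	gene00356
signaling_set_2	signaling function brain gene set (synthetic)	gene00964	gene00473	gene00364	gene00173	gene00626	gene00120	gene00506	gene00061	gene00224	gene00787
neural_set_1	neural function brain gene set (synthetic)	gene00133	gene00757	gene00254	gene00408	gene00401	gene00939	gene00893	gene00509	gene00083	gene00171	gene00460	gene00412	gene00563	gene00285	gene00905	gene00141	gene00839	gene00441	gene00885
neural_set_2	neural function brain gene set (synthetic)	gene00724	gene00426	gene00368	gene00700	gene00906	gene00390	gene00981	gene00237	gene00155	gene00085	gene00181	gene00238	gene00675	gene00239	gene00013	gene00497	gene00852	gene00604
metabolic_set_1	metabolic function brain gene set (synthetic)	gene00270	gene00289	gene00005	gene00150	gene00430	gene00548	gene00379	gene00625	gene00580	gene00327	gene00976	gene00129	gene00708	gene00880	gene00528
metabolic_set_2	metabolic function brain gene set (synthetic)	gene00468	gene00922	gene00892	gene00799	gene00975	gene00896	gene00697	gene00818	gene00573	gene00402	gene00408
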