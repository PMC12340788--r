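name	x	y	z
E1	0.630327	0.621267	-0.465526
E2	0.601327	0.783245	-0.157901
E3	0.437724	0.885599	0.155279
E4	0.336255	0.859068	0.385920
E5	0.186646	0.740638	0.645461
E6	0.000000	0.541558	0.840663
E7	-0.173058	0.246405	0.953591
E8	0.435247	0.843550	-0.314617
E9	0.284322	0.956576	-0.064207
E10	0.198999	0.966524	0.161958
E11	0.000000	0.924943	0.380106
E12	-0.186646	0.740638	0.645461
E13	-0.335538	0.473570	0.814338
E14	0.125810	0.956874	-0.261849
E15	0.000000	0.999232	-0.039195
E16	0.000000	0.988630	0.150368
E17	0.000000	0.924148	-0.382035
E18	-0.198999	0.966524	0.161958
E19	-0.336255	0.859068	0.385920
E20	-0.490608	0.680332	0.544474
E21	-0.125810	0.956874	-0.261849
E22	-0.284322	0.956576	-0.064207
E23	-0.437724	0.885599	0.155279
E24	-0.550981	0.766634	0.329685
E25	-0.435247	0.843550	-0.314617
E26	-0.601327	0.783245	-0.157901
E27	-0.702858	0.697225	0.140950
E28	-0.727046	0.569071	0.384139
E29	-0.659464	0.399021	0.637095
E30	-0.521890	0.161564	0.837572
E31	-0.273136	-0.069955	0.959428
E32	-0.630327	0.621267	-0.465526
E33	-0.801451	0.539913	-0.257234
E34	-0.903545	0.417355	0.097066
E35	-0.879294	0.229424	0.417380
E36	-0.758346	0.064853	0.648618
E37	-0.532658	-0.181929	0.826545
E38	-0.719820	0.417027	-0.554930
E39	-0.932766	0.134075	-0.334622
E40	-0.997756	0.029125	0.060286
E41	-0.918727	-0.082137	0.386256
E42	-0.777609	-0.281399	0.562262
E43	-0.659956	0.263306	-0.703653
E44	-0.782010	0.167144	-0.600436
E45	-0.930696	-0.214385	-0.296383
E46	-0.956725	-0.276707	0.090053
E47	-0.873083	-0.366504	0.321561
E48	-0.513066	0.208405	-0.832665
E49	-0.628745	0.059924	-0.775299
E50	-0.844723	-0.478239	-0.240271
E51	-0.818364	-0.559477	0.131401
E52	-0.733465	-0.542271	0.409842
E53	-0.539696	-0.495923	0.680286
E54	-0.298305	-0.424479	0.854887
E55	0.000000	-0.265615	0.964079
E56	-0.626660	-0.230827	-0.744322
E57	-0.745447	-0.402824	-0.531077
E58	-0.720397	-0.665176	-0.196390
E59	-0.631792	-0.759219	0.156287
E60	-0.510803	-0.729298	0.455197
E61	-0.297089	-0.671158	0.679180
E62	0.000000	-0.806013	0.591898
E63	-0.536419	-0.414250	-0.735290
E64	-0.594617	-0.625711	-0.504892
E65	-0.538551	-0.822779	-0.181653
E66	-0.428071	-0.887613	0.169996
E67	-0.224919	-0.874339	0.430049
E68	-0.375909	-0.617486	-0.690944
E69	-0.376421	-0.791424	-0.481618
E70	-0.305078	-0.938384	-0.162365
E71	-0.164894	-0.968716	0.185470
E72	0.000000	-0.931301	0.364252
E73	-0.189298	-0.717457	-0.670389
E74	-0.119709	-0.879588	-0.460428
E75	0.000000	-0.990720	-0.135915
E76	0.164894	-0.968716	0.185470
E77	0.224919	-0.874339	0.430049
E78	0.297089	-0.671158	0.679180
E79	0.298305	-0.424479	0.854887
E80	0.273136	-0.069955	0.959428
E81	0.000000	-0.756154	-0.654394
E82	0.119709	-0.879588	-0.460428
E83	0.305078	-0.938384	-0.162365
E84	0.428071	-0.887613	0.169996
E85	0.510803	-0.729298	0.455197
E86	0.539696	-0.495923	0.680286
E87	0.532658	-0.181929	0.826545
E88	0.189298	-0.717457	-0.670389
E89	0.376421	-0.791424	-0.481618
E90	0.538551	-0.822779	-0.181653
E91	0.631792	-0.759219	0.156287
E92	0.733465	-0.542271	0.409842
E93	0.777609	-0.281399	0.562262
E94	0.375909	-0.617486	-0.690944
E95	0.594617	-0.625711	-0.504892
E96	0.720397	-0.665176	-0.196390
E97	0.818364	-0.559477	0.131401
E98	0.873083	-0.366504	0.321561
E99	0.536419	-0.414250	-0.735290
E100	0.745447	-0.402824	-0.531077
E101	0.844723	-0.478239	-0.240271
E102	0.956725	-0.276707	0.090053
E103	0.918727	-0.082137	0.386256
E104	0.758346	0.064853	0.648618
E105	0.521890	0.161564	0.837572
E106	0.173058	0.246405	0.953591
E107	0.626660	-0.230827	-0.744322
E108	0.930696	-0.214385	-0.296383
E109	0.997756	0.029125	0.060286
E110	0.879294	0.229424	0.417380
E111	0.659464	0.399021	0.637095
E112	0.335538	0.473570	0.814338
E113	0.628745	0.059924	-0.775299
E114	0.782010	0.167144	-0.600436
E115	0.932766	0.134075	-0.334622
E116	0.903545	0.417355	0.097066
E117	0.727046	0.569071	0.384139
E118	0.490608	0.680332	0.544474
E119	0.513066	0.208405	-0.832665
E120	0.659956	0.263306	-0.703653
E121	0.719820	0.417027	-0.554930
E122	0.801451	0.539913	-0.257234
E123	0.702858	0.697225	0.140950
E124	0.550981	0.766634	0.329685
E125	0.621616	0.478266	-0.620367
E126	0.330381	0.603027	-0.726090
E127	-0.330381	0.603027	-0.726090
E128	-0.621616	0.478266	-0.620367
Cz	0.000000	0.025487	0.999675
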