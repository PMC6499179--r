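species	variant	n0	n1	n2	n3	n4plus
glyma	full	553	1933	6531	1697	3995
phavu	full	826	8748	3981	716	438
aradu	full	2264	7761	3390	752	542
Nissc	full	1425	8472	3656	681	475
medtr	full	1001	8141	3545	984	1038
tripr	full	1252	8255	3429	957	816
lotja	full	1873	7602	3444	1138	652
chafa	full	2558	7894	3178	591	488
mimpu	full	3859	6432	2858	846	714
bauto	full	4066	5921	2570	1130	1022
cerca	full	1557	10567	1708	437	440
glyma	collapsed	553	7951	4217	1163	825
phavu	collapsed	826	9034	3911	616	322
aradu	collapsed	2265	7907	3396	707	434
Nissc	collapsed	1427	8815	3621	545	301
medtr	collapsed	1003	8806	3443	798	659
tripr	collapsed	1254	8878	3285	791	501
lotja	collapsed	1873	9018	3066	534	218
chafa	collapsed	2559	8353	2970	484	343
mimpu	collapsed	3860	7934	2160	430	325
bauto	collapsed	4067	7475	2362	546	259
cerca	collapsed	1558	10988	1564	342	257
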