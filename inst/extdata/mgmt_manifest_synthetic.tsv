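probe_id	chromosome	position	on_hm27	on_hm450
cgsim0001	10	131264750	FALSE	TRUE
cgsim0002	10	131264850	TRUE	TRUE
cgsim0003	10	131264950	FALSE	TRUE
cgsim0004	10	131265050	FALSE	TRUE
cg02022136	10	131265100	FALSE	TRUE
cgsim0005	10	131265150	TRUE	TRUE
cgsim0006	10	131265250	FALSE	TRUE
cgsim0007	10	131265350	FALSE	TRUE
cgsim0008	10	131265450	TRUE	TRUE
cg12434587	10	131265519	TRUE	TRUE
cg12981137	10	131265575	TRUE	TRUE
cgsim0009	10	131265650	FALSE	TRUE
cg23998405	10	131265700	FALSE	TRUE
cgsim0010	10	131265850	TRUE	TRUE
cgsim0011	10	131265950	FALSE	TRUE
cgsim0012	10	131266050	FALSE	TRUE
cgsim0013	10	131266150	FALSE	TRUE
cgsim0014	10	131266250	TRUE	TRUE
cgsim0015	10	131264699	FALSE	TRUE
cgsim0016	10	131400000	TRUE	TRUE
cgsim0017	10	131266301	FALSE	TRUE
cgsim0018	7	50000000	FALSE	TRUE
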