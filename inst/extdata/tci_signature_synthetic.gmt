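TCI_SYNTHETIC	synthetic 160-gene T cell-inflamed placeholder	TCI001	TCI002	TCI003	TCI004	TCI005	TCI006	TCI007	TCI008	TCI009	TCI010	TCI011	TCI012	TCI013	TCI014	TCI015	TCI016	TCI017	TCI018	TCI019	TCI020	TCI021	TCI022	TCI023	TCI024	TCI025	TCI026	TCI027	TCI028	TCI029	TCI030	TCI031	TCI032	TCI033	TCI034	TCI035	TCI036	TCI037	TCI038	TCI039	TCI040	TCI041	TCI042	TCI043	TCI044	TCI045	TCI046	TCI047	TCI048	TCI049	TCI050	TCI051	TCI052	TCI053	TCI054	TCI055	TCI056	TCI057	TCI058	TCI059	TCI060	TCI061	TCI062	TCI063	TCI064	TCI065	TCI066	TCI067	TCI068	TCI069	TCI070	TCI071	TCI072	TCI073	TCI074	TCI075	TCI076	TCI077	TCI078	TCI079	TCI080	TCI081	TCI082	TCI083	TCI084	TCI085	TCI086	TCI087	TCI088	TCI089	TCI090	TCI091	TCI092	TCI093	TCI094	TCI095	TCI096	TCI097	TCI098	TCI099	TCI100	TCI101	TCI102	TCI103	TCI104	TCI105	TCI106	TCI107	TCI108	TCI109	TCI110	TCI111	TCI112	TCI113	TCI114	TCI115	TCI116	TCI117	TCI118	TCI119	TCI120	TCI121	TCI122	TCI123	TCI124	TCI125	TCI126	TCI127	TCI128	TCI129	TCI130	TCI131	TCI132	TCI133	TCI134	TCI135	TCI136	TCI137	TCI138	TCI139	TCI140	TCI141	TCI142	TCI143	TCI144	TCI145	TCI146	TCI147	TCI148	TCI149	TCI150	TCI151	TCI152	TCI153	TCI154	TCI155	TCI156	TCI157	TCI158	TCI159	TCI160
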