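region_id	hemisphere	functional_network
L_001	L	Cingulo-opercular
L_002	L	Cingulo-opercular
L_003	L	Cingulo-opercular
L_004	L	Cingulo-opercular
L_005	L	Cingulo-opercular
L_006	L	Cingulo-opercular
L_007	L	Cingulo-opercular
L_008	L	Cingulo-opercular
L_009	L	Cingulo-opercular
L_010	L	Cingulo-opercular
L_011	L	Cingulo-opercular
L_012	L	Cingulo-opercular
L_013	L	Cingulo-opercular
L_014	L	Cingulo-opercular
L_015	L	Cingulo-opercular
L_016	L	Cingulo-opercular
L_017	L	Cingulo-opercular
L_018	L	Cingulo-opercular
L_019	L	Cingulo-opercular
L_020	L	Cingulo-opercular
L_021	L	Cingulo-opercular
L_022	L	Cingulo-opercular
L_023	L	Cingulo-opercular
L_024	L	Cingulo-opercular
L_025	L	Cingulo-opercular
L_026	L	Cingulo-opercular
L_027	L	Cingulo-opercular
L_028	L	Cingulo-opercular
L_029	L	Orbito-affective
L_030	L	Orbito-affective
L_031	L	Orbito-affective
L_032	L	Dorsal attention
L_033	L	Dorsal attention
L_034	L	Dorsal attention
L_035	L	Dorsal attention
L_036	L	Dorsal attention
L_037	L	Dorsal attention
L_038	L	Dorsal attention
L_039	L	Dorsal attention
L_040	L	Dorsal attention
L_041	L	Dorsal attention
L_042	L	Dorsal attention
L_043	L	Dorsal attention
L_044	L	Frontoparietal
L_045	L	Frontoparietal
L_046	L	Frontoparietal
L_047	L	Frontoparietal
L_048	L	Frontoparietal
L_049	L	Frontoparietal
L_050	L	Frontoparietal
L_051	L	Frontoparietal
L_052	L	Frontoparietal
L_053	L	Frontoparietal
L_054	L	Frontoparietal
L_055	L	Frontoparietal
L_056	L	Frontoparietal
L_057	L	Frontoparietal
L_058	L	Frontoparietal
L_059	L	Frontoparietal
L_060	L	Frontoparietal
L_061	L	Frontoparietal
L_062	L	Frontoparietal
L_063	L	Frontoparietal
L_064	L	Frontoparietal
L_065	L	Frontoparietal
L_066	L	Frontoparietal
L_067	L	Frontoparietal
L_068	L	Frontoparietal
L_069	L	Other
L_070	L	Other
L_071	L	Other
L_072	L	Other
L_073	L	Other
L_074	L	Other
L_075	L	Other
L_076	L	Other
L_077	L	Other
L_078	L	Other
L_079	L	Other
L_080	L	Other
L_081	L	Other
L_082	L	Other
L_083	L	Other
L_084	L	Other
L_085	L	Other
L_086	L	Other
L_087	L	Other
L_088	L	Other
L_089	L	Other
L_090	L	Other
L_091	L	Other
L_092	L	Other
L_093	L	Other
L_094	L	Other
L_095	L	Other
L_096	L	Other
L_097	L	Other
L_098	L	Other
L_099	L	Other
L_100	L	Other
L_101	L	Other
L_102	L	Other
L_103	L	Other
L_104	L	Other
L_105	L	Other
L_106	L	Other
L_107	L	Other
L_108	L	Other
L_109	L	Other
L_110	L	Other
L_111	L	Other
L_112	L	Other
L_113	L	Other
L_114	L	Other
L_115	L	Other
L_116	L	Other
L_117	L	Other
L_118	L	Other
L_119	L	Other
L_120	L	Other
L_121	L	Other
L_122	L	Other
L_123	L	Other
L_124	L	Other
L_125	L	Other
L_126	L	Other
L_127	L	Other
L_128	L	Other
L_129	L	Other
L_130	L	Other
L_131	L	Other
L_132	L	Other
L_133	L	Other
L_134	L	Other
L_135	L	Other
L_136	L	Other
L_137	L	Other
L_138	L	Other
L_139	L	Other
L_140	L	Other
L_141	L	Other
L_142	L	Other
L_143	L	Other
L_144	L	Other
L_145	L	Other
L_146	L	Other
L_147	L	Other
L_148	L	Other
L_149	L	Other
L_150	L	Other
L_151	L	Other
L_152	L	Other
L_153	L	Other
L_154	L	Other
L_155	L	Other
L_156	L	Other
L_157	L	Other
L_158	L	Other
L_159	L	Other
L_160	L	Other
L_161	L	Other
L_162	L	Other
L_163	L	Other
L_164	L	Other
L_165	L	Other
L_166	L	Other
L_167	L	Other
L_168	L	Other
L_169	L	Other
L_170	L	Other
L_171	L	Other
L_172	L	Other
L_173	L	Other
L_174	L	Other
L_175	L	Other
L_176	L	Other
L_177	L	Other
L_178	L	Other
L_179	L	Other
L_180	L	Other
R_001	R	Cingulo-opercular
R_002	R	Cingulo-opercular
R_003	R	Cingulo-opercular
R_004	R	Cingulo-opercular
R_005	R	Cingulo-opercular
R_006	R	Cingulo-opercular
R_007	R	Cingulo-opercular
R_008	R	Cingulo-opercular
R_009	R	Cingulo-opercular
R_010	R	Cingulo-opercular
R_011	R	Cingulo-opercular
R_012	R	Cingulo-opercular
R_013	R	Cingulo-opercular
R_014	R	Cingulo-opercular
R_015	R	Cingulo-opercular
R_016	R	Cingulo-opercular
R_017	R	Cingulo-opercular
R_018	R	Cingulo-opercular
R_019	R	Cingulo-opercular
R_020	R	Cingulo-opercular
R_021	R	Cingulo-opercular
R_022	R	Cingulo-opercular
R_023	R	Cingulo-opercular
R_024	R	Cingulo-opercular
R_025	R	Cingulo-opercular
R_026	R	Cingulo-opercular
R_027	R	Cingulo-opercular
R_028	R	Cingulo-opercular
R_029	R	Orbito-affective
R_030	R	Orbito-affective
R_031	R	Orbito-affective
R_032	R	Dorsal attention
R_033	R	Dorsal attention
R_034	R	Dorsal attention
R_035	R	Dorsal attention
R_036	R	Dorsal attention
R_037	R	Dorsal attention
R_038	R	Dorsal attention
R_039	R	Dorsal attention
R_040	R	Dorsal attention
R_041	R	Dorsal attention
R_042	R	Dorsal attention
R_043	R	Frontoparietal
R_044	R	Frontoparietal
R_045	R	Frontoparietal
R_046	R	Frontoparietal
R_047	R	Frontoparietal
R_048	R	Frontoparietal
R_049	R	Frontoparietal
R_050	R	Frontoparietal
R_051	R	Frontoparietal
R_052	R	Frontoparietal
R_053	R	Frontoparietal
R_054	R	Frontoparietal
R_055	R	Frontoparietal
R_056	R	Frontoparietal
R_057	R	Frontoparietal
R_058	R	Frontoparietal
R_059	R	Frontoparietal
R_060	R	Frontoparietal
R_061	R	Frontoparietal
R_062	R	Frontoparietal
R_063	R	Frontoparietal
R_064	R	Frontoparietal
R_065	R	Frontoparietal
R_066	R	Frontoparietal
R_067	R	Frontoparietal
R_068	R	Other
R_069	R	Other
R_070	R	Other
R_071	R	Other
R_072	R	Other
R_073	R	Other
R_074	R	Other
R_075	R	Other
R_076	R	Other
R_077	R	Other
R_078	R	Other
R_079	R	Other
R_080	R	Other
R_081	R	Other
R_082	R	Other
R_083	R	Other
R_084	R	Other
R_085	R	Other
R_086	R	Other
R_087	R	Other
R_088	R	Other
R_089	R	Other
R_090	R	Other
R_091	R	Other
R_092	R	Other
R_093	R	Other
R_094	R	Other
R_095	R	Other
R_096	R	Other
R_097	R	Other
R_098	R	Other
R_099	R	Other
R_100	R	Other
R_101	R	Other
R_102	R	Other
R_103	R	Other
R_104	R	Other
R_105	R	Other
R_106	R	Other
R_107	R	Other
R_108	R	Other
R_109	R	Other
R_110	R	Other
R_111	R	Other
R_112	R	Other
R_113	R	Other
R_114	R	Other
R_115	R	Other
R_116	R	Other
R_117	R	Other
R_118	R	Other
R_119	R	Other
R_120	R	Other
R_121	R	Other
R_122	R	Other
R_123	R	Other
R_124	R	Other
R_125	R	Other
R_126	R	Other
R_127	R	Other
R_128	R	Other
R_129	R	Other
R_130	R	Other
R_131	R	Other
R_132	R	Other
R_133	R	Other
R_134	R	Other
R_135	R	Other
R_136	R	Other
R_137	R	Other
R_138	R	Other
R_139	R	Other
R_140	R	Other
R_141	R	Other
R_142	R	Other
R_143	R	Other
R_144	R	Other
R_145	R	Other
R_146	R	Other
R_147	R	Other
R_148	R	Other
R_149	R	Other
R_150	R	Other
R_151	R	Other
R_152	R	Other
R_153	R	Other
R_154	R	Other
R_155	R	Other
R_156	R	Other
R_157	R	Other
R_158	R	Other
R_159	R	Other
R_160	R	Other
R_161	R	Other
R_162	R	Other
R_163	R	Other
R_164	R	Other
R_165	R	Other
R_166	R	Other
R_167	R	Other
R_168	R	Other
R_169	R	Other
R_170	R	Other
R_171	R	Other
R_172	R	Other
R_173	R	Other
R_174	R	Other
R_175	R	Other
R_176	R	Other
R_177	R	Other
R_178	R	Other
R_179	R	Other
R_180	R	Other
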