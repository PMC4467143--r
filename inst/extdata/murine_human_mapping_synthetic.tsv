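assay_id	human_id
mmu-assay-0001	miR-001
mmu-assay-0002	miR-002
mmu-assay-0003	miR-003
mmu-assay-0004	miR-004
mmu-assay-0005	miR-005
mmu-assay-0006	miR-006
mmu-assay-0007	miR-007
mmu-assay-0008	miR-008
mmu-assay-0009	miR-009
mmu-assay-0010	miR-010
mmu-assay-0011	miR-011
mmu-assay-0012	miR-012
mmu-assay-0013	miR-013
mmu-assay-0014	miR-014
mmu-assay-0015	miR-015
mmu-assay-0016	miR-016
mmu-assay-0017	miR-017
mmu-assay-0018	miR-018
mmu-assay-0019	miR-019
mmu-assay-0020	miR-020
mmu-assay-0021	miR-021
mmu-assay-0022	miR-022
mmu-assay-0023	miR-023
mmu-assay-0024	miR-024
mmu-assay-0025	miR-025
mmu-assay-0026	miR-026
mmu-assay-0027	miR-027
mmu-assay-0028	miR-028
mmu-assay-0029	miR-029
mmu-assay-0030	miR-030
mmu-assay-0031	miR-031
mmu-assay-0032	miR-032
mmu-assay-0033	miR-033
mmu-assay-0034	miR-034
mmu-assay-0035	miR-035
mmu-assay-0036	miR-036
mmu-assay-0037	miR-037
mmu-assay-0038	miR-038
mmu-assay-0039	miR-039
mmu-assay-0040	miR-040
mmu-assay-0041	miR-041
mmu-assay-0042	miR-042
mmu-assay-0043	miR-043
mmu-assay-0044	miR-044
mmu-assay-0045	miR-045
mmu-assay-0046	miR-046
mmu-assay-0047	miR-047
mmu-assay-0048	miR-048
mmu-assay-0049	miR-049
mmu-assay-0050	miR-050
mmu-assay-0051	miR-051
mmu-assay-0052	miR-052
mmu-assay-0053	miR-053
mmu-assay-0054	miR-054
mmu-assay-0055	miR-055
mmu-assay-0056	miR-056
mmu-assay-0057	miR-057
mmu-assay-0058	miR-058
mmu-assay-0059	miR-059
mmu-assay-0060	miR-060
mmu-assay-0061	miR-061
mmu-assay-0062	miR-062
mmu-assay-0063	miR-063
mmu-assay-0064	miR-064
mmu-assay-0065	miR-065
mmu-assay-0066	miR-066
mmu-assay-0067	miR-067
mmu-assay-0068	miR-068
mmu-assay-0069	miR-069
mmu-assay-0070	miR-070
mmu-assay-0071	miR-071
mmu-assay-0072	miR-072
mmu-assay-0073	miR-073
mmu-assay-0074	miR-074
mmu-assay-0075	miR-075
mmu-assay-0076	miR-076
mmu-assay-0077	miR-077
mmu-assay-0078	miR-078
mmu-assay-0079	miR-079
mmu-assay-0080	miR-080
mmu-assay-0081	miR-081
mmu-assay-0082	miR-082
mmu-assay-0083	miR-083
mmu-assay-0084	miR-084
mmu-assay-0085	miR-085
mmu-assay-0086	miR-086
mmu-assay-0087	miR-087
mmu-assay-0088	miR-088
mmu-assay-0089	miR-089
mmu-assay-0090	miR-090
mmu-assay-0091	miR-091
mmu-assay-0092	miR-092
mmu-assay-0093	miR-093
mmu-assay-0094	miR-094
mmu-assay-0095	miR-095
mmu-assay-0096	miR-096
mmu-assay-0097	miR-097
mmu-assay-0098	miR-098
mmu-assay-0099	miR-099
mmu-assay-0100	miR-100
mmu-assay-0101	miR-101
mmu-assay-0102	miR-102
mmu-assay-0103	miR-103
mmu-assay-0104	miR-104
mmu-assay-0105	miR-105
mmu-assay-0106	miR-106
mmu-assay-0107	miR-107
mmu-assay-0108	miR-108
mmu-assay-0109	miR-109
mmu-assay-0110	miR-110
mmu-assay-0111	miR-111
mmu-assay-0112	miR-112
mmu-assay-0113	miR-113
mmu-assay-0114	miR-114
mmu-assay-0115	miR-115
mmu-assay-0116	miR-116
mmu-assay-0117	miR-117
mmu-assay-0118	miR-118
mmu-assay-0119	miR-119
mmu-assay-0120	miR-120
mmu-assay-0121	miR-121
mmu-assay-0122	miR-122
mmu-assay-0123	miR-123
mmu-assay-0124	miR-124
mmu-assay-0125	miR-125
mmu-assay-0126	miR-126
mmu-assay-0127	miR-127
mmu-assay-0128	miR-128
mmu-assay-0129	miR-129
mmu-assay-0130	miR-130
mmu-assay-0131	miR-131
mmu-assay-0132	miR-132
mmu-assay-0133	miR-133
mmu-assay-0134	miR-134
mmu-assay-0135	miR-135
mmu-assay-0136	miR-136
mmu-assay-0137	miR-137
mmu-assay-0138	miR-138
mmu-assay-0139	miR-139
mmu-assay-0140	miR-140
mmu-assay-0141	miR-141
mmu-assay-0142	miR-142
mmu-assay-0143	miR-143
mmu-assay-0144	miR-144
mmu-assay-0145	miR-145
mmu-assay-0146	miR-146
mmu-assay-0147	miR-147
mmu-assay-0148	miR-148
mmu-assay-0149	miR-149
mmu-assay-0150	miR-150
mmu-assay-0151	miR-151
mmu-assay-0152	miR-152
mmu-assay-0153	miR-153
mmu-assay-0154	miR-154
mmu-assay-0155	miR-155
mmu-assay-0156	miR-156
mmu-assay-0157	miR-157
mmu-assay-0158	miR-158
mmu-assay-0159	miR-159
mmu-assay-0160	miR-160
mmu-assay-0161	miR-161
mmu-assay-0162	miR-162
mmu-assay-0163	miR-163
mmu-assay-0164	miR-164
mmu-assay-0165	miR-165
mmu-assay-0166	miR-166
mmu-assay-0167	miR-167
mmu-assay-0168	miR-168
mmu-assay-0169	miR-169
mmu-assay-0170	miR-170
mmu-assay-0171	miR-171
mmu-assay-0172	miR-172
mmu-assay-0173	miR-173
mmu-assay-0174	miR-174
mmu-assay-0175	miR-175
mmu-assay-0176	miR-176
mmu-assay-0177	miR-177
mmu-assay-0178	miR-178
mmu-assay-0179	miR-179
mmu-assay-0180	miR-180
mmu-assay-0181	miR-181
mmu-assay-0182	miR-182
mmu-assay-0183	miR-183
mmu-assay-0184	miR-184
mmu-assay-0185	miR-185
mmu-assay-0186	miR-186
mmu-assay-0187	miR-187
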