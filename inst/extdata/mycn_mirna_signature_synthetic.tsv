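mirna_id	direction
miR-001	1
miR-002	1
miR-003	1
miR-004	1
miR-005	1
miR-006	1
miR-007	1
miR-008	1
miR-009	1
miR-010	1
miR-011	1
miR-012	1
miR-013	1
miR-014	1
miR-015	1
miR-016	1
miR-017	1
miR-018	1
miR-019	1
miR-020	1
miR-021	1
miR-022	1
miR-023	1
miR-024	1
miR-025	1
miR-026	1
miR-027	1
miR-028	1
miR-029	1
miR-030	1
miR-031	1
miR-032	1
miR-033	1
miR-034	1
miR-035	1
miR-036	-1
miR-037	-1
miR-038	-1
miR-039	-1
miR-040	-1
miR-041	-1
miR-042	-1
miR-043	-1
miR-044	-1
miR-045	-1
miR-046	-1
miR-047	-1
miR-048	-1
miR-049	-1
miR-050	-1
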