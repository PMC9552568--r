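system	code	category	wildcard	label
ICD9	282.41	SCD	FALSE	Sickle cell thalassemia without crisis
ICD9	282.42	SCD	FALSE	Sickle cell thalassemia with crisis
ICD9	282.6	SCD	FALSE	Sickle cell disease unspecified
ICD9	282.61	SCD	FALSE	Sickle cell/Hb-SS disease without crisis
ICD9	282.62	SCD	FALSE	Sickle cell/Hb-SS disease with crisis
ICD9	282.63	SCD	FALSE	Sickle cell/Hb-C disease without crisis
ICD9	282.64	SCD	FALSE	Sickle cell/Hb-C disease with crisis
ICD9	282.68	SCD	FALSE	Other sickle cell disease without crisis
ICD9	282.69	SCD	FALSE	Other sickle cell disease with crisis
ICD9	282.5	TRAIT	FALSE	Sickle cell trait
ICD10	D57	SCD	FALSE	Sickle cell disorders
ICD10	D57.0	SCD	TRUE	Sickle cell anemia with crisis
ICD10	D57.1	SCD	TRUE	Sickle cell anemia without crisis
ICD10	D57.2	SCD	TRUE	Double heterozygous sickling disorders
ICD10	D57.4	SCD	TRUE	Sickle cell thalassemia
ICD10	D57.8	SCD	TRUE	Other sickle cell disorders
ICD10	D57.3	TRAIT	TRUE	Sickle cell trait
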