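factor	category	count	pct
year	2015	2	0.10
year	2016	2	0.10
year	2017	104	5.45
year	2018	194	10.16
year	2019	252	13.20
year	2020	224	11.73
year	2021	284	14.88
year	2022	400	20.95
year	2023	373	19.54
year	2024	74	3.88
gender	female	501	26.24
gender	male	1214	63.59
gender	unknown	194	10.16
age	<18	2	0.10
age	18-45	41	2.15
age	45-65	434	22.73
age	65-75	528	27.66
age	>=75	465	24.36
age	unknown	439	23.00
reporter	physician	1344	70.40
reporter	pharmacist	266	13.93
reporter	consumer	192	10.06
reporter	other health professional	96	5.03
reporter	unknown	11	0.58
country	other	772	40.44
country	united states	550	28.81
country	japan	273	14.30
country	france	181	9.48
country	united kingdom	133	6.97
route	intravenous	856	44.84
route	other	771	40.39
route	intravenous drip	282	14.77
outcome	hospitalization	700	34.81
outcome	other serious	664	33.02
outcome	death	505	25.11
outcome	life-threatening	111	5.52
outcome	disability	27	1.34
outcome	required intervention	4	0.20
time_to_onset	<7	194	14.59
time_to_onset	7-28	167	12.56
time_to_onset	28-60	157	11.80
time_to_onset	>=60	397	29.85
time_to_onset	unknown	415	31.20
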