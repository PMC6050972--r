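name	value	unit	source
k_plus3	21.875	1/s	assumed
K_3	13	1	literature
K_w	0.082	1/mM	assumed
k_w	4000	1/s	assumed
dG_w	-2.45	kBT	assumed
k_on_amp	29.875	1/s	assumed
sigma_on	100	nm	assumed
x_on_shift	3.5	nm	assumed
capture_range	3	nm	assumed
lambda_cut	0.4	nm	assumed
dG_on	0.7	kBT	literature
dG_on_ref	0.7	kBT	literature
k_Pplus	250	1/s	literature
lambda_P	0.65	nm	assumed
lambda_P_bleb	0.65	nm	assumed
k_Pplus_bleb	250	1/s	literature
k_Pi	20000	1/s	assumed
K_P	0.3	1/mM	assumed
k_HL	160	1/s	assumed
k_D0	1000	1/s	assumed
lambda_D	2	nm	assumed
k_ADP	1250	1/s	assumed
k_T	6500	1/(mM s)	assumed
k_basal	0.00625	1/s	assumed
k_bfast	10000	1/s	assumed
K_bind	1	1/uM	literature
k_brel	500	1/s	assumed
power_stroke_factor	1	1	assumed
kT	3.84	pN nm	assumed
kappa	2	pN/nm	assumed
x_pre	7	nm	assumed
x_DH	2	nm	assumed
G_AMpDP	-7	kBT	assumed
G_AMsDP	-7.05	kBT	assumed
G_AMDL	-7.1	kBT	assumed
G_AMDH	-23.1	kBT	assumed
G_AMD	-23.6	kBT	assumed
G_AM	-24.1	kBT	assumed
dG_ATP	25	kBT	assumed
rate_cap	1e+05	1/s	assumed
MgATP	1	mM	literature
Pi	0.5	mM	assumed
actin	0	mM	assumed
bleb	0	uM	literature
d_repeat	36	nm	literature
sites_per_repeat	3	1	literature
density	80	heads/um	assumed
temperature_regime	5C		literature
kon_scope	bleb_only		assumed
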