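term	measure	class	study_id	hr	ci_low	ci_high	p
n_cnvs_all	n_cnvs	all	discovery	0.991	0.919	1.068	0.811
n_cnvs_all	n_cnvs	all	replication	1.001	0.928	1.080	0.997
n_cnvs_all	n_cnvs	all	joint_printed	0.996	0.944	1.050	0.879
n_cnvs_del	n_cnvs	deletion	discovery	1.049	0.957	1.150	0.307
n_cnvs_del	n_cnvs	deletion	replication	1.163	0.959	1.409	0.124
n_cnvs_del	n_cnvs	deletion	joint_printed	1.069	0.984	1.162	0.113
n_cnvs_dup	n_cnvs	duplication	discovery	0.917	0.814	1.034	0.158
n_cnvs_dup	n_cnvs	duplication	replication	0.985	0.912	1.063	0.697
n_cnvs_dup	n_cnvs	duplication	joint_printed	0.965	0.905	1.029	0.275
avg_len_all	avg_len	all	discovery	1.025	1.009	1.041	0.002
avg_len_all	avg_len	all	replication	1.012	0.963	1.062	0.644
avg_len_all	avg_len	all	joint_printed	1.024	1.009	1.039	0.002
avg_len_del	avg_len	deletion	discovery	1.015	1.002	1.027	0.023
avg_len_del	avg_len	deletion	replication	1.007	0.980	1.035	0.598
avg_len_del	avg_len	deletion	joint_printed	1.014	1.003	1.025	0.013
avg_len_dup	avg_len	duplication	discovery	1.011	1.003	1.020	0.008
avg_len_dup	avg_len	duplication	replication	1.009	0.977	1.042	0.597
avg_len_dup	avg_len	duplication	joint_printed	1.011	1.003	1.019	0.005
total_len_all	total_len	all	discovery	1.006	0.998	1.015	0.146
total_len_all	total_len	all	replication	1.004	0.993	1.015	0.523
total_len_all	total_len	all	joint_printed	1.005	0.999	1.012	0.107
total_len_del	total_len	deletion	discovery	1.011	1.000	1.023	0.050
total_len_del	total_len	deletion	replication	1.009	1.004	1.014	0.001
total_len_del	total_len	deletion	joint_printed	1.009	1.004	1.015	0.0005
total_len_dup	total_len	duplication	discovery	1.001	0.989	1.014	0.814
total_len_dup	total_len	duplication	replication	0.999	0.985	1.014	0.911
total_len_dup	total_len	duplication	joint_printed	1.000	0.991	1.009	0.973
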