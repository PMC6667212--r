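tissue	scheme	category1	category2	n1	n2	ec	description	k1	k2	p_printed	upper_bound
shoot	AR	up_up_up	down_down_down	105	166	EC:3.1.3.16	phosphatase	5	1	3.39e-02	FALSE
shoot	AR	ns_up_ns	ns_down_ns	319	404	EC:3.6.1.15	phosphatase	3	26	1e-04	TRUE
shoot	AR	ns_up_ns	ns_down_ns	319	404	EC:3.6.1.3	adenylpyrophosphatase	1	15	1.50e-03	FALSE
shoot	AR	ns_ns_up	ns_ns_down	1139	1276	EC:1.11.1.7	lactoperoxidase	4	21	1.89e-03	FALSE
shoot	AR	ns_ns_up	ns_ns_down	1139	1276	EC:3.6.1.15	phosphatase	17	50	2.70e-04	FALSE
shoot	AR	ns_ns_up	ns_ns_down	1139	1276	EC:3.6.1.3	adenylpyrophosphatase	12	35	2.87e-03	FALSE
shoot	TC	ns_up_down	ns_down_up	178	228	EC:3.6.1.15	phosphatase	2	12	2.73e-02	FALSE
shoot	TC	ns_up_down	ns_down_up	178	228	EC:3.6.1.3	adenylpyrophosphatase	0	10	3.08e-03	FALSE
shoot	TC	ns_up_ns	ns_down_ns	423	518	EC:3.6.1.15	phosphatase	4	18	1.51e-02	FALSE
shoot	TC	ns_ns_up	ns_ns_down	866	872	EC:1.11.1.7	lactoperoxidase	3	14	9.34e-04	FALSE
root	AR	ns_up	ns_down	314	528	EC:1.11.1.7	lactoperoxidase	3	21	9.68e-03	FALSE
root	AR	ns_up	ns_down	314	528	EC:4.1.1.2	decarboxylase	0	20	6.73e-04	FALSE
root	AR	ns_up_up	ns_down_down	156	330	EC:1.11.1.7	lactoperoxidase	1	12	7.05e-02	FALSE
root	AR	ns_up_up	ns_down_down	156	330	EC:4.1.1.2	decarboxylase	0	18	1.25e-03	FALSE
root	AR	ns_ns_up	ns_ns_down	1805	1761	EC:1.11.1.7	lactoperoxidase	9	44	1e-04	TRUE
root	AR	ns_ns_up	ns_ns_down	1805	1761	EC:3.6.1.15	phosphatase	39	86	1e-04	TRUE
root	AR	ns_ns_up	ns_ns_down	1805	1761	EC:3.6.1.3	adenylpyrophosphatase	33	63	1.28e-03	FALSE
root	TC	ns_ns_up	ns_ns_down	1274	1625	EC:3.1.3.16	phosphatase	18	9	1.93e-02	FALSE
root	TC	ns_ns_up	ns_ns_down	1274	1625	EC:1.11.1.7	lactoperoxidase	6	45	1e-04	TRUE
root	TC	ns_ns_up	ns_ns_down	1274	1625	EC:3.6.1.15	phosphatase	28	87	1e-04	TRUE
root	TC	ns_ns_up	ns_ns_down	1274	1625	EC:3.6.1.3	adenylpyrophosphatase	21	65	1.60e-04	FALSE
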