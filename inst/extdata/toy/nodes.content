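t01	1.0	0.2	-0.3	-0.3	c0
t02	1.0	-0.2	0.0	0.2	c0
t03	1.0	0.5	0.3	0.7	c0
t04	1.0	0.1	0.6	-0.5	c0
t05	1.0	-0.3	-0.4	0.0	c0
t06	1.0	0.4	-0.1	0.5	c0
t07	1.0	0.0	0.2	-0.7	c0
t08	1.0	-0.4	0.5	-0.2	c0
t09	1.0	0.3	-0.5	0.3	c0
t10	1.0	-0.1	-0.2	0.8	c0
t11	1.0	-0.5	0.1	-0.4	c0
t12	1.0	0.2	0.4	0.1	c0
t13	1.0	-0.2	-0.6	0.6	c0
t14	1.0	0.5	-0.3	-0.6	c0
t15	1.0	0.1	0.0	-0.1	c0
t16	-1.0	-0.3	0.3	0.4	c1
t17	-1.0	0.4	0.6	-0.8	c1
t18	-1.0	0.0	-0.4	-0.3	c1
t19	-1.0	-0.4	-0.1	0.2	c1
t20	-1.0	0.3	0.2	0.7	c1
t21	-1.0	-0.1	0.5	-0.5	c1
t22	-1.0	-0.5	-0.5	0.0	c1
t23	-1.0	0.2	-0.2	0.5	c1
t24	-1.0	-0.2	0.1	-0.7	c1
t25	-1.0	0.5	0.4	-0.2	c1
t26	-1.0	0.1	-0.6	0.3	c1
t27	-1.0	-0.3	-0.3	0.8	c1
t28	-1.0	0.4	0.0	-0.4	c1
t29	-1.0	0.0	0.3	0.1	c1
t30	-1.0	-0.4	0.6	0.6	c1
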