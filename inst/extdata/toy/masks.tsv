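t01	train
t02	test
t03	test
t04	train
t05	test
t06	test
t07	train
t08	test
t09	test
t10	train
t11	test
t12	test
t13	train
t14	test
t15	test
t16	train
t17	test
t18	test
t19	train
t20	test
t21	test
t22	train
t23	test
t24	test
t25	train
t26	test
t27	test
t28	train
t29	test
t30	test
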