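t01	t05
t01	t09
t01	t14
t01	t15
t02	t05
t02	t10
t02	t15
t03	t06
t03	t10
t03	t12
t04	t07
t04	t08
t04	t12
t05	t11
t05	t13
t05	t15
t06	t09
t06	t10
t07	t08
t07	t11
t07	t14
t07	t15
t08	t11
t09	t13
t10	t13
t12	t15
t14	t15
t16	t19
t16	t20
t16	t29
t16	t30
t17	t21
t17	t24
t17	t25
t17	t28
t18	t22
t18	t24
t18	t26
t18	t28
t19	t22
t19	t27
t20	t23
t20	t29
t20	t30
t21	t24
t21	t29
t22	t26
t23	t26
t23	t27
t25	t28
t25	t29
t26	t27
t29	t30
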