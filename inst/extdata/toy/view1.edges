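t01	t02
t01	t03
t01	t04
t01	t05
t01	t06
t01	t07
t01	t08
t01	t09
t01	t10
t01	t11
t01	t12
t01	t13
t01	t14
t01	t15
t02	t03
t02	t04
t02	t05
t02	t06
t02	t07
t02	t08
t02	t09
t02	t10
t02	t11
t02	t12
t02	t13
t02	t14
t02	t15
t03	t04
t03	t05
t03	t06
t03	t07
t03	t08
t03	t09
t03	t10
t03	t11
t03	t12
t03	t13
t03	t14
t03	t15
t04	t05
t04	t06
t04	t07
t04	t08
t04	t09
t04	t10
t04	t11
t04	t12
t04	t13
t04	t14
t04	t15
t05	t06
t05	t07
t05	t08
t05	t09
t05	t10
t05	t11
t05	t12
t05	t13
t05	t14
t05	t15
t06	t07
t06	t08
t06	t09
t06	t10
t06	t11
t06	t12
t06	t13
t06	t14
t06	t15
t07	t08
t07	t09
t07	t10
t07	t11
t07	t12
t07	t13
t07	t14
t07	t15
t08	t09
t08	t10
t08	t11
t08	t12
t08	t13
t08	t14
t08	t15
t09	t10
t09	t11
t09	t12
t09	t13
t09	t14
t09	t15
t10	t11
t10	t12
t10	t13
t10	t14
t10	t15
t11	t12
t11	t13
t11	t14
t11	t15
t12	t13
t12	t14
t12	t15
t13	t14
t13	t15
t14	t15
t16	t17
t16	t18
t16	t19
t16	t20
t16	t21
t16	t22
t16	t23
t16	t24
t16	t25
t16	t26
t16	t27
t16	t28
t16	t29
t16	t30
t17	t18
t17	t19
t17	t20
t17	t21
t17	t22
t17	t23
t17	t24
t17	t25
t17	t26
t17	t27
t17	t28
t17	t29
t17	t30
t18	t19
t18	t20
t18	t21
t18	t22
t18	t23
t18	t24
t18	t25
t18	t26
t18	t27
t18	t28
t18	t29
t18	t30
t19	t20
t19	t21
t19	t22
t19	t23
t19	t24
t19	t25
t19	t26
t19	t27
t19	t28
t19	t29
t19	t30
t20	t21
t20	t22
t20	t23
t20	t24
t20	t25
t20	t26
t20	t27
t20	t28
t20	t29
t20	t30
t21	t22
t21	t23
t21	t24
t21	t25
t21	t26
t21	t27
t21	t28
t21	t29
t21	t30
t22	t23
t22	t24
t22	t25
t22	t26
t22	t27
t22	t28
t22	t29
t22	t30
t23	t24
t23	t25
t23	t26
t23	t27
t23	t28
t23	t29
t23	t30
t24	t25
t24	t26
t24	t27
t24	t28
t24	t29
t24	t30
t25	t26
t25	t27
t25	t28
t25	t29
t25	t30
t26	t27
t26	t28
t26	t29
t26	t30
t27	t28
t27	t29
t27	t30
t28	t29
t28	t30
t29	t30
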