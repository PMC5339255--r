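gene	x	y
G01	0.297118	0.296493
G02	0.400323	0.000000
G03	0.594638	1.000000
G04	0.918968	0.000000
G05	0.235436	0.620960
G06	0.909494	0.302627
G07	0.954243	0.849331
G08	0.679702	0.406032
G09	0.649063	1.000000
G10	0.100181	0.117211
G11	0.239669	0.000000
G12	0.211046	0.346084
G13	0.705100	0.461808
G14	0.412014	0.000000
G15	0.785124	0.000000
G16	0.521871	0.154173
G17	0.734731	1.000000
G18	1.000000	0.000000
G19	0.407982	0.336119
G20	0.792582	0.852569
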