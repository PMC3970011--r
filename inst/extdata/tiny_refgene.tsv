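NM_000001	ALPHA	chr1	+	10000	12000	10200	11800
NM_000004	ALPHAB	chr1	+	10000	13000	10500	12800
NM_000002	BETA	chr1	-	20000	22000	20200	21800
NM_000003	GAMMA	chr1	+	300	1500	300	1400
NM_000005	DELTA	chr2	+	50000	55000	50100	54000
NM_000006	EPSILON	chr2	-	60000	64000	60500	63500
NM_000007	ZETA	chr2	+	70000	72000	70000	71500
NM_000008	ETA	chr1	+	30000	31000	30100	30900
NM_000009	THETA	chr2	-	80000	82000	80200	81000
XM_000010	IOTA	chr1	+	40000	42000	40100	41900
NM_000011	KAPPA	chrM	+	100	1000	200	900
NM_000012	LAMBDA	chr2	-	90000	92000	90100	91500
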