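name	value	unit	provenance	description
Faraday	96485.3415	C/mmol	reference model	Faraday constant
Rgas	8314.472	mJ/(mol*K)	reference model	gas constant
Temp	310	K	reference model	absolute temperature
Cm	0.185	uF	reference model	membrane capacitance
Vc	0.016404	uL	reference model	cytosolic volume
Vsr	0.001094	uL	reference model	sarcoplasmic reticulum volume
Vss	0.00005468	uL	reference model	subsarcolemmal (dyadic) volume
Ko	5.4	mM	reference model	extracellular potassium
Nao	140	mM	reference model	extracellular sodium
Cao	2	mM	reference model	extracellular calcium
GNa	14.838	nS/pF	reference model	fast sodium conductance
GK1	5.405	nS/pF	reference model	inward rectifier conductance
Gto	0.294	nS/pF	reference model	transient outward conductance (epicardial)
GKr	0.153	nS/pF	reference model	rapid delayed rectifier conductance
GKs	0.392	nS/pF	reference model	slow delayed rectifier conductance (epicardial)
pKNa	0.03	dimensionless	reference model	IKs Na permeability ratio
GCaL	0.0000398	L/(F*ms)	reference model	whole-cell L-type conductance scale
GbNa	0.00029	nS/pF	reference model	background sodium conductance
GbCa	0.000592	nS/pF	reference model	background calcium conductance
GpK	0.0146	nS/pF	reference model	plateau potassium conductance
GpCa	0.1238	pA/pF	reference model	sarcolemmal calcium pump maximum
KpCa	0.0005	mM	reference model	sarcolemmal calcium pump affinity
PNaK	2.724	pA/pF	reference model	Na/K pump maximum
KmK	1	mM	reference model	Na/K pump K affinity
KmNa	40	mM	reference model	Na/K pump Na affinity
kNaCa	1000	pA/pF	reference model	Na/Ca exchanger maximum
KmNai	87.5	mM	reference model	NCX Na affinity
KmCa	1.38	mM	reference model	NCX Ca affinity
ksat	0.1	dimensionless	reference model	NCX saturation factor
gammaNCX	0.35	dimensionless	reference model	NCX voltage-dependence position
alphaNCX	2.5	dimensionless	reference model	NCX outward-term enhancement
Vmaxup	0.006375	mM/ms	reference model	SERCA maximal uptake rate
Kup	0.00025	mM	reference model	SERCA half-saturation (control)
Vleak	0.00036	1/ms	reference model	SR leak rate constant
Vxfer	0.0038	1/ms	reference model	subspace-to-cytosol transfer rate
Vrel	0.102	mM/ms	reference model	maximal SR release rate
Bufc	0.2	mM	reference model	cytosolic buffer concentration
Kbufc	0.001	mM	reference model	cytosolic buffer affinity
Bufsr	10	mM	reference model	SR buffer concentration
Kbufsr	0.3	mM	reference model	SR buffer affinity
Bufss	0.4	mM	reference model	subspace buffer concentration
Kbufss	0.00025	mM	reference model	subspace buffer affinity
k1prime	0.15	1/(mM^2*ms)	rate table	RyR opening rate constant
k2prime	0.045	1/(mM*ms)	rate table	RyR inactivation rate constant
k3	0.060	1/ms	rate table	RyR closing rate (O->R, I->RI)
k4	0.005	1/ms	reference model	RyR recovery rate (RI->R, I->O); see note in docs
maxsr	2.5	dimensionless	rate table	SR-load modulation upper bound
minsr	1.0	dimensionless	rate table	SR-load modulation lower bound
EC	1.5	mM	rate table	SR-load modulation half-point
gammaRyR	1	dimensionless	rate table	optional k2 modulation hook
kcasrLiteral	0	flag	package	1 = literal-product reading k1 = k1'*kcasr (sensitivity only)
ryrTimeScale	8	dimensionless	package	fitted time-scale of the R<->O and RI<->I gating pairs (matches the reference model's quasi-equilibrium open gating; cancels from equilibria)
x7	2	dimensionless	package	scale of the final C'->O opening step of the LCC scheme
gCaLScale	1	dimensionless	package	fitted whole-cell conductance factor compensating sparse channel recruitment
fSlowScale	2.5	dimensionless	package	fitted time-scale of the deep voltage-inactivation step (If2<->If)
VofsCaL	15	mV	reference model	GHK driving-force offset (deltaV = V - 15)
phi	1	dimensionless	interventions	phosphorylation multiplier
eta	1	dimensionless	interventions	LCC inactivation-rate multiplier
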