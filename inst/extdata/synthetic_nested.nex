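#NEXUS
[! synthetic fixture generated by tipsort (Mersenne-Twister RNG, seed 7) ]
begin taxa;
	dimensions ntax=20;
	taxlabels
	'A'[&!name="Group4",!color=#A52A2A]
	B[&!name=Group4,!color=#a52a2a]
	'C'[&!name="Group4",!color=#ff0000]
	D[&!color=#ff0000,!name="Group4",!highlight="false"]
	E[&!color=-65536,!name=Group4]
	F[&!name="Group4",!color=-16181]
	'G'[&!color=#ffc0cb,!name="Group4"]
	H
	I
	J[&!name=Group2,!color=-16711936]
	K[&!color=#00ff00,!name=Group2]
	L[&!color=#00FF00,!name=Group2]
	'M'[&!name=Group3,!color=-16711936]
	N[&!name=Group3,!color=#00ff00]
	O[&!name=Group3,!color=#00FF00]
	P[&!color=#0000FF]
	'Q'[&!color=#0000ff]
	R[&!name=Group1]
	'S'[&!name="Group1"]
	T[&!name=Group1]
;
end;

begin trees;
	tree tree_1 = [&R] ((((G:0.340,B:0.972):0.287,(((R:0.295,E:0.997):0.774,((C:0.490,L:0.971):0.904,A:0.320):0.628):0.469,O:0.482):0.601):0.888,F:0.879):0.388,((((P:0.847,((J:0.116,S:0.070):0.009,M:0.986):0.498):0.187,((K:0.773,D:0.096):0.264,N:0.186):0.391):0.504,H:0.764):0.568,(T:0.898,(I:0.457,Q:0.799):0.966):0.443):0.079);
end;

begin figtree;
	set appearance.branchLineWidth=1.0;
end;
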