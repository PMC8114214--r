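	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	1	0.858571	0.237538	0.2296	0.403403	0.868446	0.471442	0.500412	0.184291	0.507718	0.605124	0.520733	0.815053	0.489048	0.169915	0.890818	0.863251	0.699768	0.193682	0.367422
C	0.858571	1	0.126371	0.140801	0.614974	0.60638	0.36006	0.73735	0.133909	0.758061	0.801221	0.31689	0.708415	0.358089	0.132946	0.659212	0.730793	0.890799	0.301078	0.477557
D	0.237538	0.126371	1	0.939103	0.070512	0.303306	0.381355	0.06297	0.069759	0.067379	0.120412	0.534275	0.341363	0.459199	0.062384	0.375515	0.35405	0.094948	0.068704	0.141545
E	0.2296	0.140801	0.939103	1	0.109441	0.256077	0.450989	0.089108	0.085828	0.096042	0.165818	0.52525	0.364078	0.521827	0.079763	0.354004	0.377245	0.118778	0.123413	0.217626
F	0.403403	0.614974	0.070512	0.109441	1	0.197528	0.341135	0.923343	0.150032	0.946647	0.933471	0.185907	0.431112	0.302353	0.158204	0.301029	0.46368	0.804474	0.742838	0.775862
G	0.868446	0.60638	0.303306	0.256077	0.197528	1	0.457532	0.242997	0.180126	0.255028	0.355908	0.628706	0.787197	0.504315	0.164778	0.938136	0.792317	0.395298	0.102399	0.235309
H	0.471442	0.36006	0.381355	0.450989	0.341135	0.457532	1	0.267987	0.59574	0.292854	0.4683	0.866255	0.770351	0.986292	0.586599	0.662218	0.778922	0.321256	0.399431	0.618676
I	0.500412	0.73735	0.06297	0.089108	0.923343	0.242997	0.267987	1	0.108206	0.991616	0.904765	0.164344	0.419192	0.24172	0.109098	0.329475	0.465225	0.940139	0.505824	0.581955
K	0.184291	0.133909	0.069759	0.085828	0.150032	0.180126	0.59574	0.108206	1	0.118769	0.200379	0.443607	0.338761	0.521783	0.982381	0.282139	0.345501	0.125586	0.206967	0.30673
L	0.507718	0.758061	0.067379	0.096042	0.946647	0.255028	0.292854	0.991616	0.118769	1	0.939242	0.178422	0.455114	0.265434	0.122173	0.347788	0.493178	0.930983	0.556471	0.639942
M	0.605124	0.801221	0.120412	0.165818	0.933471	0.355908	0.4683	0.904765	0.200379	0.939242	1	0.306246	0.639665	0.434739	0.207608	0.490632	0.670514	0.893096	0.657928	0.805303
N	0.520733	0.31689	0.534275	0.52525	0.185907	0.628706	0.866255	0.164344	0.443607	0.178422	0.306246	1	0.759942	0.91829	0.41322	0.780705	0.766788	0.236775	0.182398	0.35615
P	0.815053	0.708415	0.341363	0.364078	0.431112	0.787197	0.770351	0.419192	0.338761	0.455114	0.639665	0.759942	1	0.795281	0.337268	0.927922	0.98176	0.54781	0.336205	0.585874
Q	0.489048	0.358089	0.459199	0.521827	0.302353	0.504315	0.986292	0.24172	0.521783	0.265434	0.434739	0.91829	0.795281	1	0.511571	0.704414	0.796003	0.302064	0.346947	0.56665
R	0.169915	0.132946	0.062384	0.079763	0.158204	0.164778	0.586599	0.109098	0.982381	0.122173	0.207608	0.41322	0.337268	0.511571	1	0.263692	0.334037	0.122511	0.237179	0.337949
S	0.890818	0.659212	0.375515	0.354004	0.301029	0.938136	0.662218	0.329475	0.282139	0.347788	0.490632	0.780705	0.927922	0.704414	0.263692	1	0.941829	0.48285	0.191112	0.384017
T	0.863251	0.730793	0.35405	0.377245	0.46368	0.792317	0.778922	0.465225	0.345501	0.493178	0.670514	0.766788	0.98176	0.796003	0.334037	0.941829	1	0.604145	0.337035	0.5812
V	0.699768	0.890799	0.094948	0.118778	0.804474	0.395298	0.321256	0.940139	0.125586	0.930983	0.893096	0.236775	0.54781	0.302064	0.122511	0.48285	0.604145	1	0.394127	0.529963
W	0.193682	0.301078	0.068704	0.123413	0.742838	0.102399	0.399431	0.505824	0.206967	0.556471	0.657928	0.182398	0.336205	0.346947	0.237179	0.191112	0.337035	0.394127	1	0.906089
Y	0.367422	0.477557	0.141545	0.217626	0.775862	0.235309	0.618676	0.581955	0.30673	0.639942	0.805303	0.35615	0.585874	0.56665	0.337949	0.384017	0.5812	0.529963	0.906089	1
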