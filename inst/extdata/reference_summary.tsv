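variable	unit	mean	sd	min	max
dm_fresh	g/kg fresh	566	272.3	323	809
n	g/kg DM	64	36.4	35	124
ndf	g/kg DM	643	105.4	499	867
adf	g/kg DM	329	46.7	281	401
ee	g/kg DM	33	8.9	17	50
ash	g/kg DM	62	8.2	51	75
ge	MJ/kg DM	17.55	0.45	17.03	18.25
dmd	g/g	0.655	0.088	0.476	0.831
ged	MJ/MJ	0.652	0.104	0.461	0.829
omd	g/g	0.681	0.071	0.550	0.773
nd	g/g	0.557	0.202	0.327	0.793
ndfd	g/g	0.702	0.064	0.542	0.811
adfd	g/g	0.648	0.056	0.519	0.773
domd	g/g	0.622	0.076	0.499	0.731
de	MJ/kg DM	11.53	2.15	8.03	15.21
me	MJ/kg DM	9.89	1.84	6.33	13.36
de_ge	MJ/MJ	0.648	0.092	0.461	0.839
me_ge	MJ/MJ	0.556	0.093	0.363	0.737
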