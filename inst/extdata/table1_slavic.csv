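language,meaning,cognate_id,value
Slovene,two,dwo,1
Polish,two,dwo,1
Czech,two,dwo,1
Ukrainian,two,dwo,1
Rusyn,two,dwo,1
Slovene,belly,terh1,1
Polish,belly,terh1,0
Czech,belly,terh1,0
Ukrainian,belly,terh1,0
Rusyn,belly,terh1,0
Slovene,belly,bhreus,0
Polish,belly,bhreus,1
Czech,belly,bhreus,1
Ukrainian,belly,bhreus,0
Rusyn,belly,bhreus,0
Slovene,belly,gweh3,0
Polish,belly,gweh3,0
Czech,belly,gweh3,0
Ukrainian,belly,gweh3,1
Rusyn,belly,gweh3,0
Slovene,belly,kwehl,0
Polish,belly,kwehl,0
Czech,belly,kwehl,0
Ukrainian,belly,kwehl,0
Rusyn,belly,kwehl,1
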