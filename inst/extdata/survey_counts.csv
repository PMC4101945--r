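fence_id,fence_w_m,fence_h_m,quadrat_id,quadrat_side_m,year,count
I,200,200,1,10,2008,0
I,200,200,2,10,2008,4
I,200,200,3,10,2008,6
I,200,200,4,10,2008,1
II,200,200,1,10,2008,2
II,200,200,2,10,2008,1
II,200,200,3,10,2008,3
II,200,200,4,10,2008,4
III,150,150,1,10,2008,1
III,150,150,2,10,2008,1
III,150,150,3,10,2008,2
III,150,150,4,10,2008,0
IV,200,200,1,10,2008,2
IV,200,200,2,10,2008,2
IV,200,200,3,10,2008,0
IV,200,200,4,10,2008,1
IX,200,200,1,10,2008,3
IX,200,200,2,10,2008,5
IX,200,200,3,10,2008,8
IX,200,200,4,10,2008,3
V,200,200,1,10,2008,3
V,200,200,2,10,2008,3
V,200,200,3,10,2008,3
V,200,200,4,10,2008,5
VI,200,200,1,10,2008,10
VI,200,200,2,10,2008,3
VI,200,200,3,10,2008,1
VI,200,200,4,10,2008,1
VII,200,200,1,10,2008,4
VII,200,200,2,10,2008,4
VII,200,200,3,10,2008,6
VII,200,200,4,10,2008,3
VIII,200,200,1,10,2008,0
VIII,200,200,2,10,2008,0
VIII,200,200,3,10,2008,0
VIII,200,200,4,10,2008,0
X,200,200,1,10,2008,2
X,200,200,2,10,2008,2
X,200,200,3,10,2008,2
X,200,200,4,10,2008,3
I,200,200,1,10,2010,0
I,200,200,2,10,2010,6
I,200,200,3,10,2010,10
I,200,200,4,10,2010,2
II,200,200,1,10,2010,6
II,200,200,2,10,2010,2
II,200,200,3,10,2010,5
II,200,200,4,10,2010,8
III,150,150,1,10,2010,4
III,150,150,2,10,2010,3
III,150,150,3,10,2010,1
III,150,150,4,10,2010,3
IV,200,200,1,10,2010,2
IV,200,200,2,10,2010,0
IV,200,200,3,10,2010,0
IV,200,200,4,10,2010,1
IX,200,200,1,10,2010,3
IX,200,200,2,10,2010,4
IX,200,200,3,10,2010,13
IX,200,200,4,10,2010,3
V,200,200,1,10,2010,5
V,200,200,2,10,2010,6
V,200,200,3,10,2010,3
V,200,200,4,10,2010,8
VI,200,200,1,10,2010,18
VI,200,200,2,10,2010,4
VI,200,200,3,10,2010,2
VI,200,200,4,10,2010,0
VII,200,200,1,10,2010,7
VII,200,200,2,10,2010,5
VII,200,200,3,10,2010,10
VII,200,200,4,10,2010,1
VIII,200,200,1,10,2010,0
VIII,200,200,2,10,2010,0
VIII,200,200,3,10,2010,0
VIII,200,200,4,10,2010,0
X,200,200,1,10,2010,3
X,200,200,2,10,2010,1
X,200,200,3,10,2010,1
X,200,200,4,10,2010,2
I,200,200,1,10,2011,2
I,200,200,2,10,2011,7
I,200,200,3,10,2011,5
I,200,200,4,10,2011,1
II,200,200,1,10,2011,1
II,200,200,2,10,2011,0
II,200,200,3,10,2011,0
II,200,200,4,10,2011,2
III,150,150,1,10,2011,0
III,150,150,2,10,2011,4
III,150,150,3,10,2011,4
III,150,150,4,10,2011,1
IV,200,200,1,10,2011,0
IV,200,200,2,10,2011,12
IV,200,200,3,10,2011,4
IV,200,200,4,10,2011,1
IX,200,200,1,10,2011,4
IX,200,200,2,10,2011,2
IX,200,200,3,10,2011,4
IX,200,200,4,10,2011,3
V,200,200,1,10,2011,1
V,200,200,2,10,2011,1
V,200,200,3,10,2011,6
V,200,200,4,10,2011,6
VI,200,200,1,10,2011,0
VI,200,200,2,10,2011,5
VI,200,200,3,10,2011,5
VI,200,200,4,10,2011,4
VII,200,200,1,10,2011,1
VII,200,200,2,10,2011,5
VII,200,200,3,10,2011,3
VII,200,200,4,10,2011,4
VIII,200,200,1,10,2011,4
VIII,200,200,2,10,2011,0
VIII,200,200,3,10,2011,1
VIII,200,200,4,10,2011,3
X,200,200,1,10,2011,3
X,200,200,2,10,2011,4
X,200,200,3,10,2011,4
X,200,200,4,10,2011,5
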