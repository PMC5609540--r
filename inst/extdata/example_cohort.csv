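# synthetic example cohort (20 patients, hand-constructed; not patient data)
# seed: none (fixed values)
id,diplotype,cyp2c9,cyp3a5,ethnicity,age,tam_ngml,dmt_ngml,ohtam_ngml,e_ngml
P001,*1x2/*1,*1/*1,*1/*3,Caucasian,44,118,195,1.9,29.5
P002,*1/*1,*1/*1,*3/*3,Caucasian,57,131,210,2.1,22.4
P003,*1/*1,*1/*2,*3/*3,Caucasian,39,102,168,1.5,18.9
P004,*1/*1,*1/*1,*3/*3,Asian,61,125,201,1.8,20.2
P005,*1/*41,*1/*3,*3/*3,Caucasian,48,98,158,1.4,12.1
P006,*1/*41,*1/*1,*1/*3,Arab,52,140,226,2.2,13.8
P007,*1/*10,*1/*1,*3/*3,Asian,45,115,182,1.7,11.2
P008,*1/*10,*2/*3,*3/*3,Asian,50,120,190,1.2,10.6
P009,*1/*4,*1/*1,*3/*3,Caucasian,63,108,176,1.6,10.9
P010,*1/*4,*1/*2,*1/*3,Caucasian,41,95,149,1.3,9.8
P011,*1/*4,*1/*1,*3/*3,Caucasian,55,133,214,2.0,11.5
P012,*1/*4,*3/*3,*3/*3,Arab,47,111,180,1.0,9.1
P013,*41/*41,*1/*1,*3/*3,Caucasian,59,127,205,1.9,10.2
P014,*10/*10,*1/*1,*3/*3,Asian,43,122,196,1.8,9.4
P015,*10/*10,*1/*3,*1/*1,Asian,49,104,167,1.5,8.8
P016,*4/*41,*1/*1,*3/*3,Caucasian,66,136,219,2.1,5.1
P017,*4/*41,*2/*2,*3/*3,Caucasian,38,99,161,0.9,4.6
P018,*4/*10,*1/*1,*1/*3,Asian,54,117,188,1.7,4.2
P019,*4/*4,*1/*1,*3/*3,Caucasian,62,129,208,1.9,3.1
P020,*4/*4,*1/*2,*3/*3,Arab,46,106,172,1.6,3.6
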