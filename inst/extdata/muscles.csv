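no,finger,name,abbreviation,f_max_N,cmc1_fe,cmc1_aa,mp1_fe,mp1_aa,ip1_fe,mp2_fe,mp2_aa,pip2,dip2,mp3_fe,mp3_aa,pip3,dip3,mp4_fe,mp4_aa,pip4,dip4,mp5_fe,mp5_aa,pip5,dip5
1,thumb,Flexor pollicis longus,FPL,2.7,14.3,0.2,13.6,-0.1,8.7,,,,,,,,,,,,,,,,
2,thumb,Extensor pollicis longus,EPL,1.3,-8.1,-9.5,-8.5,-4.4,-4.1,,,,,,,,,,,,,,,,
3,thumb,Abductor pollicis longus,ABPL,3.1,-7.1,10.5,0,0,0,,,,,,,,,,,,,,,,
4,thumb,Extensor pollicis brevis,EPB,0.8,-13,3.2,-8.6,3.2,0,,,,,,,,,,,,,,,,
5,thumb,Abductor pollicis brevis,ABPB,1.1,-3.9,16.5,2.6,16.5,0,,,,,,,,,,,,,,,,
6,thumb,Flexor pollicis brevis,FBP,1.3,13.4,10.5,8.8,10.5,0,,,,,,,,,,,,,,,,
7,thumb,Opponens pollicis,OP,1.9,12.9,4.8,0,4.8,0,,,,,,,,,,,,,,,,
8,thumb,Adductor pollicis transverse,APt,3,36.9,-20.6,9.7,-20.6,0,,,,,,,,,,,,,,,,
9,thumb,Adductor pollicis oblique,APo,3,27,-17,8.2,-17,0,,,,,,,,,,,,,,,,
10,index,Flexor digitorum superficialis 2,FDS2,2,,,,,,11.9,1.7,13.6,0,,,,,,,,,,,,
11,index,Flexor digitorum profundus 2,FDP2,2.7,,,,,,10.2,0.4,-8.5,4,,,,,,,,,,,,
12,index,Extensor digitorum communis 2,EDC2,1,,,,,,-9.4,0.7,0,-1.6,,,,,,,,,,,,
13,index,Extensor indicis,EI,1,,,,,,-9.4,0.7,-8.6,-1.6,,,,,,,,,,,,
14,index,1st lumbrical,1LU,0.2,,,,,,9.6,-9.9,2.6,-2,,,,,,,,,,,,
15,index,1st palmar interossei,1PI,1.3,,,,,,6.4,8.8,8.8,-2,,,,,,,,,,,,
16,index,1st dorsal interossei,1DI,3.2,,,,,,4.4,-9.6,0,0,,,,,,,,,,,,
17,middle,Flexor digitorum superficialis 3,FDS3,3.4,,,,,,,,,,11.5,0.6,5.3,0,,,,,,,,
18,middle,Flexor digitorum profundus 3,FDP3,3.4,,,,,,,,,,9.2,0.2,7.1,4.2,,,,,,,,
19,middle,Extensor digitorum communis 3,EDC3,1.9,,,,,,,,,,-9.3,-0.9,-3.3,-1.5,,,,,,,,
20,middle,2nd lumbrical,2LU,0.2,,,,,,,,,,10.5,8.2,-2.8,-1.9,,,,,,,,
21,middle,2nd dorsal interossei,2DI,2.5,,,,,,,,,,8,9.4,-1.1,-0.8,,,,,,,,
22,middle,3rd dorsal interossei,3DI,2,,,,,,,,,,3.4,-7.6,-2.6,-1.8,,,,,,,,
23,ring,Flexor digitorum superficialis 4,FDS4,2,,,,,,,,,,,,,,9.9,-1.2,5,0,,,,
24,ring,Flexor digitorum profundus 4,FDP4,3,,,,,,,,,,,,,,8.9,-0.8,6.2,4.1,,,,
25,ring,Extensor digitorum communis 4,EDC4,1.7,,,,,,,,,,,,,,-8.1,-0.5,-2.4,-1.2,,,,
26,ring,3rd lumbrical,3LU,0.1,,,,,,,,,,,,,,6.6,-7.5,-2,-1.5,,,,
27,ring,2nd palmar interossei,2PI,1.2,,,,,,,,,,,,,,3.1,-7.6,-2,-1.5,,,,
28,ring,4th dorsal interossei,4DI,1.7,,,,,,,,,,,,,,4.7,7.1,-1.2,-0.9,,,,
29,little,Flexor digitorum superficialis 5,FDS5,0.9,,,,,,,,,,,,,,,,,,8.6,3.2,4.7,0
30,little,Flexor digitorum profundus 5,FDP5,2.8,,,,,,,,,,,,,,,,,,8.5,4,5.9,3.2
31,little,Extensor digitorum communis 5,EDC5,0.9,,,,,,,,,,,,,,,,,,-4.9,0.9,-2.6,-1.3
32,little,Extensor digiti minimi,EDM,1,,,,,,,,,,,,,,,,,,-4.8,0.9,-2.6,-1.3
33,little,Abductor digiti minimi,ABDM,1.4,,,,,,,,,,,,,,,,,,4.7,-8,-2,-1.5
34,little,Flexor digiti minimi brevis,FDMB,0.4,,,,,,,,,,,,,,,,,,7.9,0,0,0
35,little,4th lumbrical,4LU,2,,,,,,,,,,,,,,,,,,6.3,7.2,-2.2,-1.7
36,little,3rd palmar interossei,3PI,1,,,,,,,,,,,,,,,,,,2.1,7.7,-2,-1.5
37,little,Opponens digiti minimi,ODM,2,,,,,,,,,,,,,,,,,,6,0,0,0
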