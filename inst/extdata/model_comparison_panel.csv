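part,mixture,odorant_a,odorant_b,oi_a,oi_b,oi_mix,oi_a_m,oi_b_m,pde,u,sc,add
A,T+E,toluene,ethylbenzene,4.3,3.1,5.5,0.70,0.76,5.0,4.7,4.3,7.4
A,T+E,toluene,ethylbenzene,3.5,4.6,4.2,0.52,0.91,5.4,5.2,4.6,8.1
A,T+E,toluene,ethylbenzene,2.1,3.1,4.1,0.46,0.95,4.4,3.4,3.1,5.2
A,T+E,toluene,ethylbenzene,2.5,2.6,3.6,0.78,0.68,3.7,3.3,2.6,5.1
A,T+E,toluene,ethylbenzene,2.1,2.6,3.0,0.71,0.75,3.5,3.0,2.6,4.7
A,E+OX,ethylbenzene,o-xylene,5.3,2.9,6.4,0.91,0.51,6.3,5.9,5.3,8.2
A,E+OX,ethylbenzene,o-xylene,5.3,2.4,5.6,1.01,0.36,6.0,5.6,5.3,7.7
A,E+OX,ethylbenzene,o-xylene,3.1,2.9,4.7,0.74,0.72,5.1,4.3,3.1,6.0
A,E+OX,ethylbenzene,o-xylene,2.6,2.9,4.1,0.50,0.92,4.4,4.0,2.9,5.5
A,E+OX,ethylbenzene,o-xylene,3.1,2.4,3.9,0.86,0.58,4.7,4.0,3.1,5.5
A,E+NP,ethylbenzene,n-propylbenzene,2.6,6.0,6.2,0.49,0.93,4.5,5.4,6.0,8.6
A,E+NP,ethylbenzene,n-propylbenzene,5.2,3.0,5.0,1.24,-0.26,5.8,5.0,5.2,8.2
A,E+NP,ethylbenzene,n-propylbenzene,4.7,3.7,4.9,1.07,0.25,5.4,5.0,4.7,8.4
A,E+NP,ethylbenzene,n-propylbenzene,3.1,3.7,4.1,0.97,0.42,4.4,4.0,3.7,6.8
A,E+NP,ethylbenzene,n-propylbenzene,2.6,3.0,2.8,1.09,0.20,2.9,3.3,3.0,5.6
A,OX+MX,o-xylene,m-xylene,6.3,2.0,6.2,1.12,0.14,5.3,6.4,6.3,8.3
A,OX+MX,o-xylene,m-xylene,2.9,4.3,5.2,0.77,0.69,4.9,5.3,4.3,7.2
A,OX+MX,o-xylene,m-xylene,4.0,3.4,5.1,0.94,0.47,4.8,5.4,4.0,7.4
A,OX+MX,o-xylene,m-xylene,2.4,2.0,3.8,0.94,0.47,3.5,3.2,2.4,4.4
A,OX+MX,o-xylene,m-xylene,1.5,3.4,3.7,0.61,0.84,3.4,3.7,3.4,4.9
B,T+S,toluene,styrene,2.1,5.0,6.3,0.29,1.05,5.4,5.3,5.0,7.1
B,T+S,toluene,styrene,1.5,5.0,5.8,0.05,1.15,5.3,5.0,5.0,6.5
B,T+S,toluene,styrene,4.2,2.6,4.5,0.98,0.41,4.1,5.0,4.2,6.8
B,T+S,toluene,styrene,2.1,4.5,4.2,0.41,0.98,4.7,4.9,4.5,6.6
B,T+S,toluene,styrene,1.5,2.6,2.7,0.60,0.85,2.7,3.0,2.6,4.1
B,E+S,ethylbenzene,styrene,5.2,4.5,6.0,0.87,0.57,6.5,6.0,5.2,9.7
B,E+S,ethylbenzene,styrene,3.1,5.0,5.7,0.58,0.87,6.0,5.1,5.0,8.1
B,E+S,ethylbenzene,styrene,4.6,4.5,5.1,0.79,0.67,5.9,5.6,4.6,9.1
B,E+S,ethylbenzene,styrene,2.6,4.5,4.5,0.44,0.96,4.8,4.5,4.5,7.1
B,E+S,ethylbenzene,styrene,3.1,3.8,4.4,0.80,0.66,4.9,4.3,3.8,6.9
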