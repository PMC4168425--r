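mixture,odorant_a,odorant_b,axis_component,a2,a1,a0,ln_oav_a,ln_oav_b,oi_a_m,oi_b_m,predicted_oi,measured_oi
T+E,toluene,ethylbenzene,ethylbenzene,1.73,-2.13,1.40,3.36,3.54,0.95,0.60,5.3,5.5
T+E,toluene,ethylbenzene,ethylbenzene,1.73,-2.13,1.40,4.05,1.75,1.25,0.16,5.3,5.5
T+E,toluene,ethylbenzene,ethylbenzene,1.73,-2.13,1.40,2.34,3.54,0.77,0.74,4.4,4.1
T+E,toluene,ethylbenzene,ethylbenzene,1.73,-2.13,1.40,2.67,2.44,1.01,0.54,4.0,3.6
T+E,toluene,ethylbenzene,ethylbenzene,1.73,-2.13,1.40,1.65,5.26,0.40,0.91,5.4,5.8
E+OX,ethylbenzene,o-xylene,ethylbenzene,1.88,-2.10,1.30,5.26,1.70,0.96,0.23,5.5,6.0
E+OX,ethylbenzene,o-xylene,ethylbenzene,1.88,-2.10,1.30,4.93,2.80,0.83,0.54,5.6,5.6
E+OX,ethylbenzene,o-xylene,ethylbenzene,1.88,-2.10,1.30,3.54,3.49,0.61,0.82,5.1,4.7
E+OX,ethylbenzene,o-xylene,ethylbenzene,1.88,-2.10,1.30,2.44,3.49,0.43,0.98,4.5,4.1
E+OX,ethylbenzene,o-xylene,ethylbenzene,1.88,-2.10,1.30,1.34,3.82,0.05,1.17,4.5,4.6
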