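site	osteoporotic	mof	hip
hip	1	1	1
femur	1	0	0
vertebra	1	1	0
wrist	1	1	0
shoulder	1	1	0
humerus	1	0	0
arm	1	0	0
ribs	1	0	0
pelvis	1	0	0
clavicle	1	0	0
scapula	1	0	0
sternum	1	0	0
tibia	1	0	0
fibula	1	0	0
skull_face	0	0	0
ankle	0	0	0
foot	0	0	0
metatarsal	0	0	0
toes	0	0	0
hand	0	0	0
fingers	0	0	0
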