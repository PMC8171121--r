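subject	age	gender	bmi	surgery	duration_min	anesthesia	chd	cvd	hypertension	dm	delirium
1	84	woman	27.5	Lumbar spine surgery	140	GA	no	no	no	no	yes
2	81	woman	26.7	Lumbar spine surgery	100	GA	no	no	no	no	no
3	83	man	25.7	Humerus fractures	155	GA	no	yes	no	no	yes
4	81	man	23.4	Lumbar spine surgery	170	GA	no	no	yes	no	no
5	93	woman	23.7	Femoral neck fracture	190	NB	yes	yes	yes	yes	yes
6	87	woman	19.5	Fracture of right femoral neck	70	NB	no	no	no	no	no
7	93	woman	20.8	Right femoral intertrochanteric fracture	80	GA	no	yes	no	no	yes
8	86	woman	18.7	Proximal fracture of left humerus	120	GA	no	yes	yes	yes	no
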