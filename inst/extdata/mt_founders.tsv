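haplogroup	motif
M	16223
D	16223
D4	16223-16362
D4j3	16223-16286-16362
D5	16189-16223
D5a2a	16172-16189-16223
G	16223-16362
G2a	16223-16278-16362
G2b1b	16130-16223-16362
G3	16223-16274-16362
G3a1	16215-16223-16274-16362
M8	16223-16298
C	16223-16298-16327
C4d	16093-16223-16298-16327
C4a2'3'4	16223-16298-16327-16357
Z	16185-16223-16260-16298
M7	16223
M7b	16129-16192-16223
M9	16223-16234
M9a	16223-16234-16316
M9a1a	16092-16223-16234-16316
M9a1b1	16145-16223-16234-16316
M9b	16167-16223-16234
M10	16223-16311
M13a1b	16148-16223-16381
M62b	16223-16305
M74a	16140-16223
M33c	16169-16223
N	
A	16290-16319
A4	16242-16290-16319
A11	16248-16290-16319
A11b	16248-16249-16290-16319
N9a	16257A-16261
R	
B4	16217
B5b	16243
F1	16304
F1a	16162-16304
U	
L3e	16223-16327
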