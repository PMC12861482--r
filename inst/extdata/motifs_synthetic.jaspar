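>SYNM01 synthetic_plant_tf_01
A [ 1 1 97 1 1 1 1 97 1 1 ]
C [ 1 1 1 97 1 97 1 1 97 1 ]
G [ 97 1 1 1 1 1 97 1 1 1 ]
T [ 1 97 1 1 97 1 1 1 1 97 ]
>SYNM02 synthetic_plant_tf_02
A [ 97 97 97 1 97 1 1 97 1 1 1 ]
C [ 1 1 1 1 1 1 1 1 1 97 1 ]
G [ 1 1 1 1 1 1 1 1 1 1 97 ]
T [ 1 1 1 97 1 97 97 1 97 1 1 ]
>SYNM03 synthetic_plant_tf_03
A [ 1 1 1 1 1 97 1 1 1 1 1 1 ]
C [ 1 97 1 1 97 1 97 1 1 1 1 1 ]
G [ 97 1 1 1 1 1 1 1 97 97 1 1 ]
T [ 1 1 97 97 1 1 1 97 1 1 97 97 ]
>SYNM04 synthetic_plant_tf_04
A [ 1 1 1 1 1 97 1 1 1 1 ]
C [ 97 97 1 97 97 1 97 97 1 97 ]
G [ 1 1 97 1 1 1 1 1 1 1 ]
T [ 1 1 1 1 1 1 1 1 97 1 ]
>SYNM05 synthetic_plant_tf_05
A [ 1 1 1 1 1 97 1 1 1 1 1 97 ]
C [ 1 97 1 1 97 1 1 1 97 1 1 1 ]
G [ 97 1 1 97 1 1 1 97 1 97 97 1 ]
T [ 1 1 97 1 1 1 97 1 1 1 1 1 ]
>SYNM06 synthetic_plant_tf_06
A [ 1 1 1 1 1 1 97 1 1 1 1 ]
C [ 97 1 1 1 1 1 1 97 1 97 1 ]
G [ 1 97 1 1 97 1 1 1 97 1 1 ]
T [ 1 1 97 97 1 97 1 1 1 1 97 ]
>SYNM07 synthetic_plant_tf_07
A [ 1 1 97 1 1 97 97 1 1 1 ]
C [ 1 1 1 97 97 1 1 1 1 1 ]
G [ 97 97 1 1 1 1 1 97 97 1 ]
T [ 1 1 1 1 1 1 1 1 1 97 ]
>SYNM08 synthetic_plant_tf_08
A [ 97 97 97 1 1 1 97 1 1 97 1 97 ]
C [ 1 1 1 1 97 97 1 1 97 1 1 1 ]
G [ 1 1 1 1 1 1 1 1 1 1 97 1 ]
T [ 1 1 1 97 1 1 1 97 1 1 1 1 ]
>SYNM09 synthetic_plant_tf_09
A [ 97 1 97 1 1 1 1 1 1 1 1 ]
C [ 1 97 1 97 1 1 1 1 1 1 97 ]
G [ 1 1 1 1 97 1 97 97 1 1 1 ]
T [ 1 1 1 1 1 97 1 1 97 97 1 ]
>SYNM10 synthetic_plant_tf_10
A [ 1 1 1 97 97 1 1 97 1 97 1 1 ]
C [ 97 1 1 1 1 97 1 1 97 1 97 97 ]
G [ 1 97 97 1 1 1 1 1 1 1 1 1 ]
T [ 1 1 1 1 1 1 97 1 1 1 1 1 ]
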