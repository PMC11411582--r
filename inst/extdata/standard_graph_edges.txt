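# node a community 1 role boundary stimulus 1
# node b community 1 role inner stimulus 2
# node c community 1 role inner stimulus 3
# node d community 1 role inner stimulus 4
# node e community 1 role boundary stimulus 5
# node f community 2 role boundary stimulus 6
# node g community 2 role inner stimulus 7
# node h community 2 role inner stimulus 8
# node i community 2 role inner stimulus 9
# node j community 2 role boundary stimulus 10
# node k community 3 role boundary stimulus 11
# node l community 3 role inner stimulus 12
# node m community 3 role inner stimulus 13
# node n community 3 role inner stimulus 14
# node o community 3 role boundary stimulus 15
a b
a c
b c
a d
b d
c d
b e
c e
d e
e f
f g
f h
g h
f i
g i
h i
g j
h j
i j
j k
k l
k m
l m
k n
l n
m n
a o
l o
m o
n o
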