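0 1
0 2
1 2
1 3
0 4
1 4
3 4
2 5
3 5
1 6
0 7
1 7
2 7
4 7
6 7
2 8
6 8
7 8
3 9
5 9
6 9
7 9
2 10
3 10
6 10
7 10
9 10
0 11
3 11
5 11
6 11
10 11
0 12
1 12
2 12
3 12
4 12
6 12
10 12
1 13
2 13
4 13
5 13
8 13
1 14
2 14
3 14
4 14
5 14
6 14
7 14
12 14
13 14
0 15
2 15
3 15
5 15
6 15
8 15
10 15
11 15
13 15
14 15
0 16
1 16
2 16
3 16
5 16
6 16
7 16
12 16
14 16
0 17
2 17
3 17
5 17
9 17
10 17
12 17
16 17
0 18
5 18
13 18
14 18
15 18
16 18
17 18
1 19
2 19
7 19
8 19
9 19
11 19
15 19
18 19
0 20
6 23
12 31
8 33
6 36
13 38
13 41
5 43
9 43
6 48
12 54
13 56
16 56
21 22
20 23
21 23
22 23
20 24
21 24
21 25
20 26
22 26
23 26
25 26
20 27
21 27
22 27
26 27
20 28
21 28
23 28
25 28
20 29
21 29
24 29
26 29
27 29
22 30
23 30
25 30
26 30
27 30
28 30
20 31
23 31
24 31
26 31
27 31
28 31
29 31
30 31
22 32
24 32
26 32
27 32
28 32
29 32
21 33
22 33
23 33
24 33
26 33
27 33
28 33
29 33
30 33
32 33
21 34
23 34
25 34
30 34
31 34
32 34
20 35
23 35
26 35
27 35
30 35
31 35
34 35
23 36
24 36
20 37
23 37
24 37
27 37
29 37
31 37
32 37
33 37
34 37
35 37
20 38
21 38
24 38
25 38
28 38
29 38
30 38
32 38
37 38
25 39
27 39
28 39
34 39
36 39
37 39
33 41
39 41
20 42
34 42
22 44
27 44
21 46
35 46
36 51
37 53
31 54
23 57
25 58
30 58
40 43
41 43
42 43
42 44
41 45
42 45
43 45
41 46
44 46
41 47
42 47
46 47
40 48
41 48
43 48
46 48
42 49
43 49
44 49
46 49
40 50
42 50
43 50
45 50
46 50
48 50
49 50
40 51
41 51
42 51
46 51
50 51
40 52
42 52
44 52
48 52
51 52
41 53
43 53
45 53
48 53
52 53
40 54
42 54
43 54
44 54
45 54
48 54
50 54
51 54
53 54
40 55
41 55
42 55
43 55
45 55
47 55
52 55
54 55
42 56
43 56
46 56
49 56
50 56
54 56
55 56
40 57
44 57
49 57
50 57
52 57
40 58
41 58
43 58
44 58
49 58
53 58
54 58
55 58
41 59
42 59
43 59
44 59
46 59
48 59
52 59
53 59
54 59
55 59
57 59
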