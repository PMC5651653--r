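day,area_mm2,scaffold
0,0.85,loop_mesh_200
2,0.92,loop_mesh_200
4,1.11,loop_mesh_200
6,1.44,loop_mesh_200
8,1.67,loop_mesh_200
10,1.82,loop_mesh_200
12,2.24,loop_mesh_200
0,0.75,loop_mesh_500
2,0.78,loop_mesh_500
4,0.80,loop_mesh_500
6,0.88,loop_mesh_500
8,0.91,loop_mesh_500
10,1.00,loop_mesh_500
12,1.17,loop_mesh_500
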