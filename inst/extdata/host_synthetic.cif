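data_synthetic_I2a_sponge
_cell_length_a 10.8500
_cell_length_b 15.0000
_cell_length_c 22.3500
_cell_angle_alpha 90.000
_cell_angle_beta 95.500
_cell_angle_gamma 90.000
loop_
_symmetry_equiv_pos_as_xyz
'x, y, z'
'1/2-x, y, -z'
'-x, -y, -z'
'1/2+x, 1/2+y, 1/2+z'
'1/2+x, -y, z'
'-x, 1/2+y, 1/2-z'
'1/2-x, 1/2-y, 1/2-z'
'x, 1/2-y, 1/2+z'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
_atom_site_occupancy
Bi1 Bi 0.362200 0.467100 0.117800 1.0000
O1W O 0.132300 0.416300 0.143400 1.0000
O1 O 0.430000 0.311300 0.140100 1.0000
C1 C 0.486000 0.225000 0.173000 1.0000
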