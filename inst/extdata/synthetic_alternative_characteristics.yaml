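disk:
  flexion:
    p1: 10.67
    p2: 0.005913
    p3: -1.685
  extension:
    p1: 5.196
    p2: 0.008417
    p3: 24.5
  lateral:
    p1: 6.929
    p2: 0.001482
    p3: 19.760000000000002
  axial:
    p1: 4.399
    p2: 0.001141
    p3: 42.380000000000003
  axial_quad: 690234060.0
  axial_lin: 659748.0
  shear_stiffness: 260000.0
  d_damp_tra: 400000.0
  d_damp_rot: 100.0
ligaments:
  ALL:
    a: 104.099999999999994
    b: -10.06
    c: -26.82
    d: 5.625
    damping_factor: 10.0
  PLL:
    a: 28.871999999999996
    b: -43.969999999999999
    c: -2.5
    d: 15.0
    damping_factor: 10.0
  FL:
    a: 28.265999999999998
    b: 4.21
    c: 54.850000000000001
    d: -11.25
    damping_factor: 10.0
  CL:
    a: 59.363999999999997
    b: 18.969999999999999
    c: -82.200000000000003
    d: 73.329999999999998
    damping_factor: 10.0
  ISL:
    a: 0.27102
    b: -3.502
    c: 0.0
    d: 0.02414
    damping_factor: 10.0
  SSL:
    a: 0.7308
    b: -22.969999999999999
    c: 0.0
    d: 1.369
    damping_factor: 10.0
  ITL:
    a: 0.0
    b: 0.0
    c: 0.0
    d: 1.0
    damping_factor: 0.0
facets:
  stiffness: 12000.0
  damping: 4000.0
  left:
    p30: -0.007975
    p03: -0.004237
    p20: -0.1823
    p02: -0.1734
    p00: 47.310000000000002
  right:
    p30: 0.01011
    p03: -0.008587
    p20: -0.1236
    p02: -0.2915
    p00: 44.259999999999998
prestrains:
  ALL: 8.0
  PLL: 10.0
  FL: 10.0
  ITL: 10.0
  CL: 10.0
  ISL: 4.0
  SSL: -6.0
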