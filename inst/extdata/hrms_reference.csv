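formula,species,calc_mz,note
C9H9F4NO3S2,M+H,320.0033,
C9H9F4NO5S2,M-H,349.9786,
C11H11F4NO6S2,M-H,391.9891,
C10H9F4NO6S2,M-H,377.9735,
C13H15F4NO6S2,M-H,420.0204,
C16H13F4NO6S2,M-H,454.0048,
C10H9F4NO4S2,M-H,345.9836,
C8H7F4NO4S2,M+H,321.9825,
C10H9F4NO5S2,M-H,361.9786,
C8H5F4NO4S2,M-H,317.9523,
C10H11F4NO3S2,M+Na,356.0009,species corrected: printed as M+H but value matches M+Na
C10H11F4NO5S2,M+H,366.0088,species corrected: printed with inconsistent sign but value matches M+H
C12H13F4NO6S2,M-H,406.0048,
C8H11NO5S2,M-H,264.0006,
C15H12F4N2O6S2,M-H,455.0000,
C11H12F4N2O5S2,M+H,393.0197,
C18H17F4N3O6S2,M+H,512.0568,
C19H19F4N3O7S2,M+Na,564.0493,
C16H14F4N2O7S2,M-H,485.0106,
C19H28F3N3O5S2,M+H,500.1495,
C18H25F3N2O6S2,M+H,487.1179,
C22H33F3N2O6S2,M+H,543.1805,
C19H27F3N2O6S2,M+H,501.1335,
C23H35F3N2O6S2,M+H,557.1961,
C26H33F3N4O6S2,M-H,617.1721,
C23H28F3N3O6S2,M+H,564.1444,
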