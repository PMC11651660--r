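id,code,formula,leaving_group_formula,warhead_class
12,VD10-35-2,C10H9F4NO6S2,C2H4O2,ester
15,AV22-48,C8H5F4NO4S2,,vinylsulfone
22,AV22-149,C23H28F3N3O6S2,C7H7NO2,carbamate
,5bx,C11H11F4NO6S2,C3H6O2,ester
,5cx,C13H15F4NO6S2,C5H10O2,ester
,5dx,C16H13F4NO6S2,C8H8O2,ester
,24ax,C15H12F4N2O6S2,C7H7NO2,carbamate
,24bx,C16H14F4N2O7S2,C8H9NO3,carbamate
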