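# shared fixture shortcuts; everything is built in code
wi_water <- builtin_fluids()$water
wi_oil <- builtin_fluids()$silicone_oil
wi_tis <- builtin_tissues()
wi_geo <- sample_geometry()

# hand-evaluated closed-form reference times (s) for the preset scenarios:
# t(h) = -(mu eps/(rho g K)) (h + hmax log(1 - h/hmax))
T_OIL_VESSELS_5CM <- 1155.2
T_WATER_LATEWOOD_10CM <- 5729.6
T_WATER_FIBERS_10CM <- 11459
T_OIL_VESSELS_10CM <- 23560
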