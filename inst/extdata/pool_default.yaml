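pool_diameter: 180
pool_depth: 60
platform_diameter: 15
platform_bearing: 45
platform_radial_offset: 45
zone1_diameter: 75
zone2_diameter: 90
zone3_diameter: 150
zone4_diameter: 180
north_reference: 0
wall_tolerance: 2
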