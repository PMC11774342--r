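# 20 MHz annular-array ophthalmic probe ("AQ20").
# native_frame_rate (8 fps of distinct content in screen captures) is a
# published figure; other values are plausible stand-ins for a 20 MHz
# annular probe. No sector block: identity in-plane geometry.
name = AQ20
center_frequency = 20
native_frame_rate = 8
imaging_depth = 50
pixel_spacing_row = 0.08
pixel_spacing_col = 0.08
psf_axial_fwhm = 0.12
psf_lateral_fwhm = 0.3
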