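# 12 MHz ophthalmic B-scan probe ("A12").
# native_frame_rate (11 fps of distinct content in screen captures) is a
# published figure; the remaining values are plausible stand-ins for a
# 12 MHz mechanical ophthalmic probe and should be edited to match the
# actual device. No sector block: in-plane geometry treated as identity
# until the probe's fan parameters are known.
name = A12
center_frequency = 12
native_frame_rate = 11
imaging_depth = 50
pixel_spacing_row = 0.1
pixel_spacing_col = 0.1
psf_axial_fwhm = 0.2
psf_lateral_fwhm = 0.5
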