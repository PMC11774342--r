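# Handheld CMUT array ("BiQ") used with its ophthalmic preset.
# All values, including the native frame rate and the sector geometry,
# are plausible stand-ins for a handheld phased/sector probe; edit to
# match the actual device. The sector block makes scan conversion active
# for this preset.
name = BiQ
center_frequency = 5
native_frame_rate = 15
imaging_depth = 60
pixel_spacing_row = 0.2
pixel_spacing_col = 0.2
psf_axial_fwhm = 0.6
psf_lateral_fwhm = 1.2
sector_apex_offset = 10
sector_angular_span = 60
sector_radial_min = 10
sector_radial_max = 70
sector_rays_per_frame = 128
sector_samples_per_ray = 256
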