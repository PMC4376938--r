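# Lazily built, cached phantom fixtures shared across test files. The
# realistic curved phantom and its segmentation are expensive, so the
# acceptance-style checks all reuse one instance.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache))
    assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

clean_straight_phantom <- function() {
  fixture("clean_straight", function() {
    generate_phantom(phantom_spec(fov_mm = c(30, 30, 15), noise_snr = 0,
                                  blur_sigma_mm = 0), seed = 101)
  })
}

# study conditions of the realistic validation: 5 mm sinusoidal
# curvature, Rician SNR 15, 0.8-1.2 multiplicative bias, >= 200 slices
realistic_phantom <- function() {
  fixture("realistic", function() {
    generate_phantom(phantom_spec(fov_mm = c(36, 36, 63), amplitude_mm = 5,
                                  noise_snr = 15, bias_range = c(0.8, 1.2)),
                     seed = 7)
  })
}

realistic_segmentation <- function() {
  fixture("realistic_seg", function() {
    ph <- realistic_phantom()
    pre <- correct_bias_field(ph$volume)
    list(pre = pre, seg = segment_cord(pre))
  })
}

realistic_straightened <- function() {
  fixture("realistic_straight", function() {
    rs <- realistic_segmentation()
    suppressWarnings(straighten_volume(rs$pre, rs$seg))
  })
}
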