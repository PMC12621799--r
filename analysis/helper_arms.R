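# Shared definition of the synthetic imaging arms: control cells are mildly
# elongated ellipses, "Nrg1-treated" cells substantially more elongated,
# three wells of 30 cells per arm. Mask generation is a pure function of
# these configs, so every script regenerates identical cells.
study_arm_configs <- function() {
  aspects <- c(control = 1.2, nrg1 = 2.0)
  out <- lapply(names(aspects), function(arm) {
    lapply(1:3, function(w) {
      list(
        config = shape_config(
          "ellipse", size_px = 25, aspect_ratio = aspects[[arm]],
          pixel_size = 0.65, rotation_deg = 40 * w,
          seed = 100L + 10L * w + as.integer(arm == "nrg1")
        ),
        n = 30L,
        well_id = sprintf("%s_w%d", arm, w)
      )
    })
  })
  names(out) <- names(aspects)
  out
}
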