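
# Canonical condition labels, in lap order.
RW_CONDITIONS <- c("regular", "LC", "KB")

# Segment blocks of a session: pelvis is a single midline sensor, the other
# three segments are instrumented bilaterally.
RW_SEGMENTS <- data.frame(
  segment = c("pelvis", "thigh", "thigh", "shank", "shank", "foot", "foot"),
  side    = c("center", "left", "right", "left", "right", "left", "right"),
  stringsAsFactors = FALSE
)

# Channel order within a segment block. Axis convention (documented in the
# vignette): x anteroposterior, y mediolateral, z vertical; the sagittal-plane
# angular velocity is the rotation about the mediolateral axis, i.e. gyr_y.
RW_CHANNELS <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")

GRAVITY <- 9.81

RW_FEATURES <- c("mean", "sd", "max", "min", "ac_main", "ac2_height", "ac2_lag")

RW_COMBOS <- list(a = RW_CHANNELS[1:3], w = RW_CHANNELS[4:6], aw = RW_CHANNELS)

RW_SEGMENT_CODES <- c(pelvis = "PL", thigh = "TH", shank = "SH", foot = "FT")
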