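# Shared fixtures, generated in code.

# a channel plan small enough for fast gradient and shape tests
tinyPlan <- function() {
  channelPlan(stemChannels = 2L, encoderChannels = c(2L, 3L, 4L),
    multipathChannels = 4L, bottleneckChannels = 4L,
    decoderChannels = c(4L, 3L, 2L))
}

# deterministic random RGB sample with a seeded binary mask
randomSample <- function(h, w, seed = 1, withFov = FALSE) {
  set.seed(seed)
  fundusSample(
    id = paste0("rnd", seed),
    image = array(runif(h * w * 3), c(h, w, 3L)),
    vesselMask = matrix(rbinom(h * w, 1, 0.3), h, w),
    fovMask = if (withFov) matrix(rbinom(h * w, 1, 0.8), h, w) else NULL)
}

# small synthetic fundus sample (fast default for pipeline tests)
smallSynthSample <- function(seed = 1, side = 64L) {
  makeSyntheticDataset(1, synthConfig(side = side, seed = seed))[[1]]
}
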