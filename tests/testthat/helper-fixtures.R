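# Fixtures are built in code: smooth random textures for registration,
# step-edge stacks for profile probes, and a small 10 x 10 m synthetic scene
# (denser weed infestation than the field default so every cover class is
# well represented at sub-scene size).

smoothField <- function(n, seed, lo = 40, hi = 190) {
  set.seed(seed)
  img <- matrix(rnorm(n * n), n, n)
  k <- outer(dnorm(seq(-3, 3, length.out = 11)),
             dnorm(seq(-3, 3, length.out = 11)))
  kk <- matrix(0, n, n)
  kk[1:11, 1:11] <- k
  f <- Re(stats::fft(stats::fft(img) * stats::fft(kk), inverse = TRUE)) /
    (n * n)
  (f - min(f)) / (max(f) - min(f)) * (hi - lo) + lo
}

# texture plus a single vertical step edge at column `edgeCol` + 0.5
edgeImage <- function(n = 96, edgeCol = n / 2, seed = 1) {
  img <- smoothField(n, seed, 40, 90)
  right <- col(img) > edgeCol
  img[right] <- img[right] + 120
  pmin(img, 255)
}

# identical texture in every band so misalignment is the only band difference
bandStack <- function(base, B = 3, master = B) {
  MultibandStack(array(rep(base, B), c(dim(base), B)),
                 seq(450, 780, length.out = B), bitDepth = 8L,
                 masterIndex = master)
}

# horizontal probe crossing the single edge, 45 samples by default
edgeSegment <- function(n = 96, edgeCol = n / 2, y = n / 2, halfLen = 22)
  c(edgeCol - halfLen, y, edgeCol + halfLen, y)

smallSceneConfig <- function(...) {
  SceneConfig(fieldWidth = 10, fieldLength = 10, nFrames = 4L,
              weedPatchDensity = 400, seed = 7L, ...)
}

.sceneCache <- new.env(parent = emptyenv())

smallScene <- function() {
  if (is.null(.sceneCache$scene))
    .sceneCache$scene <- generateScene(smallSceneConfig())
  .sceneCache$scene
}
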