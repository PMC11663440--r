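## Shared fixtures, built once per session and memoized. 3D phantoms are the
## expensive objects; everything else is cheap enough to rebuild per test.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

## default 3D phantom (untilted, right side), processed through the pipeline
refPhantom <- function() memo("ref", function() {
  sp <- phantomSpec(voxelSizeMm = 0.15, noiseSd = 8, seed = 42)
  pv <- makePhantomVolume(sp)
  bin <- binarizeVolume(pv$volume)
  al <- orientAboutLongAxis(
    alignPrincipalAxes(bin, pv$volume@intensities, sp@voxelSizeMm,
                       provenance = "ref"))
  list(pv = pv, aligned = al)
})

## the same phantom tilted by (20, 10, 5) degrees
tiltedPhantom <- function() memo("tilted", function() {
  sp <- phantomSpec(tiltEulerDeg = c(20, 10, 5), voxelSizeMm = 0.15, noiseSd = 8, seed = 42)
  pv <- makePhantomVolume(sp)
  bin <- binarizeVolume(pv$volume)
  al <- orientAboutLongAxis(
    alignPrincipalAxes(bin, pv$volume@intensities, sp@voxelSizeMm,
                       provenance = "tilted"))
  list(pv = pv, aligned = al)
})

## left-side twin: mirrored across x before processing, declared side = left
mirroredPhantom <- function() memo("mirrored", function() {
  sp <- phantomSpec(voxelSizeMm = 0.15, noiseSd = 8, seed = 42)
  pv <- makePhantomVolume(sp)
  v <- pv$volume@intensities
  v <- v[rev(seq_len(dim(v)[1])), , ]
  vol <- new("VoxelVolume", intensities = v, voxelSize = sp@voxelSizeMm,
             provenance = "mirrored")
  bin <- binarizeVolume(vol)
  al <- orientAboutLongAxis(
    alignPrincipalAxes(bin, v, sp@voxelSizeMm, provenance = "mirrored"),
    side = "left")
  list(pv = pv, aligned = al)
})

## geometry records for one aligned phantom at the standard fractions
sectionRecords <- function(fix, fractions = c(0.35, 0.5, 0.65)) {
  do.call(rbind, lapply(fractions, function(f) {
    g <- as.data.frame(sectionGeometry(extractSection(fix$aligned, f)))
    cbind(data.frame(fraction = f), g)
  }))
}

relErr <- function(x, truth) abs(x - truth) / abs(truth)
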