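# Write a small set of NIfTI log-evidence volumes to `dir` and return the
# manifest data.frame bmsRun/readEvidenceVolumes expect. `fill` is a
# function(subject, model) -> 3-D array.
writeVolumeFixture <- function(dir, n = 2, k = 2, grid = c(4, 4, 4),
                               affine = diag(c(3, 3, 3, 1)),
                               fill = function(s, m) array(0, grid)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in seq_len(n)) {
    for (m in seq_len(k)) {
      p <- file.path(dir, sprintf("s%d_m%d.nii.gz", s, m))
      BMSmaps:::writeVolume(fill(s, m), affine, p)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("sub%02d", s), model = sprintf("model%d", m),
        path = p, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
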