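# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

# tiny tsv_wide capture text: markers A, B over `frames` rows
tsv_wide_fixture <- function(rows, frame_rate = 100, labels = c("A", "B"),
                             extra_header = character()) {
  c(paste("FRAME_RATE", frame_rate, sep = "\t"),
    "START_TIME\t0",
    extra_header,
    paste(c("MARKER_NAMES", labels), collapse = "\t"),
    rows)
}

# the same 3-frame, 2-marker capture in both dialects
two_marker_fixture <- function(dir) {
  rows <- c("0\t0\t0\t10\t10\t10",
            "1\t1\t1\t11\t11\t11",
            "2\t2\t2\t12\t12\t12")
  wide <- file.path(dir, "cap.tsv")
  writeLines(tsv_wide_fixture(rows), wide)
  long <- file.path(dir, "cap.csv")
  df <- expand.grid(frame = 0:2, marker = c("A", "B"),
                    stringsAsFactors = FALSE)
  df$time <- df$frame / 100
  base <- ifelse(df$marker == "A", 0, 10)
  df$x <- base + df$frame; df$y <- df$x; df$z <- df$x
  write.csv(df[, c("frame", "time", "marker", "x", "y", "z")], long,
            row.names = FALSE, quote = FALSE)
  list(wide = wide, long = long)
}

# random rigid motion: rotation matrix (QR of a Gaussian) + translation
random_rigid <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 500))
}

apply_rigid <- function(p, rig) {
  sweep(p %*% t(rig$R), 2, -rig$t)
}

# spine quadruple with chain length 220 (two 3-4-5 triples + one 120 leg)
spine_220 <- function() {
  list(p1 = c(0, 0, 0), p2 = c(30, 40, 0),
       p3 = c(30, 40, 120), p4 = c(60, 80, 120))
}
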