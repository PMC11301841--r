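# shared fixtures, built in code at test time

# a flat rectangular band of constant intensity inside a darker background
makeBandImage <- function(height = 160L, width = 240L, bandTop = 41L,
                          bandBottom = 140L, stroma = 200, background = 20,
                          axial = 2, lateral = 12, foveaCol = NULL,
                          meridian = "vertical", laterality = "OD") {
  m <- matrix(background, height, width)
  m[bandTop:bandBottom, ] <- stroma
  if (is.null(foveaCol)) foveaCol <- as.integer(round(width / 2))
  list(bscan = BScan(m, axialSpacing = axial, lateralSpacing = lateral,
                     foveaCol = foveaCol, meridian = meridian,
                     laterality = laterality, eyeId = "fixture"),
       boundaries = ChoroidBoundaries(rep(bandTop, width),
                                      rep(bandBottom, width)))
}

# a BinarizedChoroid with prescribed labels (for metric identities)
makeBinarized <- function(labels, validCols = NULL) {
  if (is.null(validCols)) validCols <- rep(TRUE, ncol(labels))
  methods::new("BinarizedChoroid", labels = labels,
               lumenPx = sum(labels == 2L), stromaPx = sum(labels == 1L),
               validCols = validCols,
               config = list(window_px = NA_integer_, k = NA_real_))
}

# independent brute-force Niblack oracle: double loop, symmetric reflection,
# population SD -- deliberately naive, shares no code with the implementation
bruteNiblack <- function(m, w, k) {
  r <- (w - 1L) %/% 2L
  n <- nrow(m); p <- ncol(m)
  refl <- function(v, lim) {
    v[v < 1L] <- 1L - v[v < 1L]
    v[v > lim] <- 2L * lim + 1L - v[v > lim]
    v
  }
  out <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      vals <- m[refl((i - r):(i + r), n), refl((j - r):(j + r), p)]
      mu <- mean(vals)
      out[i, j] <- mu + k * sqrt(mean((vals - mu)^2))
    }
  }
  out
}

# brute-force concordance AUC by full pair enumeration (higher = disease)
bruteAUC <- function(values, labels) {
  pos <- values[as.logical(labels)]; neg <- values[!as.logical(labels)]
  tot <- 0
  for (x in pos) for (y in neg) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# eye-level table reproducing the published exclusion accounting: 1446
# eligible eyes; 17 right and 11 left eyes flagged (some with two reasons,
# so per-reason counts exceed eyes removed); 247 of the survivors are C2
makeExclusionCohort <- function() {
  n_sub <- 723L
  d <- data.frame(subject_id = rep(sprintf("S%03d", seq_len(n_sub)), each = 2L),
                  eye = rep(c("OD", "OS"), n_sub))
  for (f in c("excl_choroiditis", "excl_pcv", "excl_severe_mm",
              "excl_fce_picc", "excl_rd")) d[[f]] <- FALSE
  od <- which(d$eye == "OD")[1:17]
  d$excl_choroiditis[od[1:2]] <- TRUE
  d$excl_pcv[od[3]] <- TRUE
  d$excl_severe_mm[od[4:11]] <- TRUE          # 8 eyes
  d$excl_fce_picc[od[c(12:17, 10:11)]] <- TRUE  # 8 flags, 2 shared eyes
  os <- which(d$eye == "OS")[1:11]
  d$excl_choroiditis[os[1]] <- TRUE
  d$excl_rd[os[2]] <- TRUE
  d$excl_severe_mm[os[3:7]] <- TRUE           # 5 eyes
  d$excl_fce_picc[os[c(8:11, 7)]] <- TRUE     # 5 flags, 1 shared eye
  keepers <- !Reduce(`|`, d[grep("^excl_", names(d))])
  cat2 <- rep("C1", nrow(d))
  cat2[which(keepers)[1:247]] <- "C2"
  d$category <- cat2
  d
}
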