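# Generates inst/extdata/montage_62_1020.tsv: spherical 10-20/10-10
# positions for a standard 62-electrode cap layout on a unit-sphere head
# model. Midline electrodes sit on the nasion-inion great circle (22.5 deg
# steps from the vertex); lateral electrodes are slerp-interpolated between
# the midline electrode of their row and the equatorial end point of that
# row's coronal arc. +y = anterior, +x = right, +z = vertex.

sph <- function(inc_deg, az_deg) {
  inc <- inc_deg * pi / 180
  az <- az_deg * pi / 180
  c(sin(inc) * cos(az), sin(inc) * sin(az), cos(inc))
}

slerp <- function(a, b, f) {
  w <- acos(max(-1, min(1, sum(a * b))))
  if (w < 1e-12) return(a)
  (sin((1 - f) * w) * a + sin(f * w) * b) / sin(w)
}

# midline arc, front (az 90) over vertex to back (az 270)
mid <- list(
  FPZ = sph(90, 90), AFZ = sph(67.5, 90), FZ = sph(45, 90),
  FCZ = sph(22.5, 90), CZ = c(0, 0, 1), CPZ = sph(22.5, 270),
  PZ = sph(45, 270), POZ = sph(67.5, 270), OZ = sph(90, 270)
)

# equatorial ring azimuths (left hemisphere; right mirrors x -> -x ... note
# +x = right so left labels use az in (90, 270))
eq_az <- c(FP1 = 108, AF7 = 126, F7 = 144, FT7 = 162, T7 = 180,
           TP7 = 198, P7 = 216, PO7 = 234, O1 = 252)

rows <- list(
  AF = list(mid = "AFZ", eq = "AF7", cols = c(AF3 = 0.5)),
  F  = list(mid = "FZ", eq = "F7",
            cols = c(F1 = 0.25, F3 = 0.5, F5 = 0.75, F7 = 1)),
  FC = list(mid = "FCZ", eq = "FT7",
            cols = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75, FT7 = 1)),
  C  = list(mid = "CZ", eq = "T7",
            cols = c(C1 = 0.25, C3 = 0.5, C5 = 0.75, T7 = 1)),
  CP = list(mid = "CPZ", eq = "TP7",
            cols = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75, TP7 = 1)),
  P  = list(mid = "PZ", eq = "P7",
            cols = c(P1 = 0.25, P3 = 0.5, P5 = 0.75, P7 = 1)),
  PO = list(mid = "POZ", eq = "PO7",
            cols = c(PO3 = 0.5, PO5 = 0.75, PO7 = 1))
)

pos <- list()
for (nm in names(mid)) pos[[nm]] <- mid[[nm]]
pos[["FP1"]] <- sph(90, eq_az[["FP1"]])
pos[["O1"]] <- sph(90, eq_az[["O1"]])
for (row in rows) {
  eq_pt <- sph(90, eq_az[[row$eq]])
  for (lab in names(row$cols)) {
    pos[[lab]] <- slerp(mid[[row$mid]], eq_pt, row$cols[[lab]])
  }
}
# cerebellar electrodes sit below the equator under O1/O2
pos[["CB1"]] <- sph(112.5, eq_az[["O1"]])

mirror <- function(nm) {
  num <- as.integer(sub(".*?([0-9]+)$", "\\1", nm))
  paste0(sub("[0-9]+$", "", nm), num + 1L)
}
for (nm in names(pos)) {
  if (grepl("[0-9]$", nm)) {
    p <- pos[[nm]]
    pos[[mirror(nm)]] <- c(-p[1], p[2], p[3])
  }
}

order62 <- c("FP1", "FPZ", "FP2", "AF3", "AF4",
             "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
             "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
             "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
             "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
             "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
             "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
             "CB1", "O1", "OZ", "O2", "CB2")
stopifnot(length(order62) == 62, all(order62 %in% names(pos)))

loc <- ifelse(grepl("Z$", order62), 0L,
              ifelse(as.integer(sub(".*?([0-9]+)$", "\\1", order62)) %% 2L
                     == 1L, 1L, -1L))
xyz <- t(vapply(order62, function(nm) pos[[nm]], numeric(3)))
stopifnot(max(abs(sqrt(rowSums(xyz^2)) - 1)) < 1e-12)

out <- data.frame(name = order62, x = round(xyz[, 1], 6),
                  y = round(xyz[, 2], 6), z = round(xyz[, 3], 6),
                  location = loc)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(out, "inst/extdata/montage_62_1020.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", nrow(out), "channels\n")
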