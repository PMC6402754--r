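# shared synthetic experiment at the reference design, generated once
refExperiment <- generateExperiment(syntheticConfig(seed = 101))

# a fully noise-free configuration of the same design
noiselessConfig <- function(seed = 1) {
  syntheticConfig(spectralNoiseSd = 0, latentCV = 0, agronomicCV = 0,
                  deltaSSd = 0, seed = seed)
}

# small random dataset for oracle checks: bands x samples
randomDataset <- function(nBand, nSample, seed, start = 400) {
  set.seed(seed)
  g <- WavelengthGrid(start, start + nBand - 1, 1)
  R <- matrix(runif(nBand * nSample, 0.05, 0.6), nBand, nSample)
  keys <- data.frame(season = 1, irrigation = 1, density = 350,
                     replicate = seq_len(nSample))
  SpectralDataset(R, g, keys)
}

# independent hand-coded evaluation of the twenty built-in indices:
# direct arithmetic on reflectances addressed by wavelength position
oracleIndexValues <- function(s, wl) {
  at <- function(l) s[which(wl == l)]
  nd <- function(a, b) (at(a) - at(b)) / (at(a) + at(b))
  c(NDI_548_522 = nd(548, 522), NDI_626_386 = nd(626, 386),
    NDI_680_1650 = nd(680, 1650), NDI_840_818 = nd(840, 818),
    NDI_1226_670 = nd(1226, 670), NDI_1382_670 = nd(1382, 670),
    NDI_1450_900 = nd(1450, 900), NDI_1650_920 = nd(1650, 920),
    NDI_2450_2100 = nd(2450, 2100), NDI_2498_1450 = nd(2498, 1450),
    NDI_2500_2250 = nd(2500, 2250), NDI_2500_2470 = nd(2500, 2470),
    MSI = at(1600) / at(820),
    SRWI = at(860) / at(1240),
    NWI3 = nd(970, 880),
    NDVI = nd(900, 685),
    NDMI = nd(2200, 1100),
    NMDI = (at(860) - (at(1640) - at(2130))) /
           (at(860) + (at(1640) - at(2130))),
    OSAVI = (at(800) - at(670)) / (at(800) + at(670) + 0.16),
    MTVI = 1.2 * (1.2 * (at(800) - at(550)) - 2.5 * (at(670) - at(550))))
}

# per-pair least-squares oracle for the R2 map, via lm()
oracleR2 <- function(R, trait, i, j) {
  nd <- (R[i, ] - R[j, ]) / (R[i, ] + R[j, ])
  if (sd(nd) < 1e-10) return(NA_real_)
  summary(lm(trait ~ nd))$r.squared
}
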