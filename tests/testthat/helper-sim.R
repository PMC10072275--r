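# shared fixture builders (everything synthetic, built at test time)

# noiseless power-law trace
powerTrace <- function(a = 1000, b = -0.05, n = 100, frameRate = 10,
                       stim = numeric()) {
  CaTrace(a * (seq_len(n))^b, frameRate, stim = stim)
}

# resting recording carrying Poisson minis, analyzed to a dff trace
restingDff <- function(seed, rateHz = 0.5, ampMean = 0.2, ampSd = 0,
                       noiseSd = 20, duration = 20, bleachB = -0.05) {
  cfg <- simConfig("postsynaptic", duration = duration, stim = c(0, 0, 0),
                   bleach = c(1000, bleachB),
                   mini = list(rateHz = rateHz, ampMean = ampMean,
                               ampSd = ampSd),
                   noise = list(gaussianSd = noiseSd), seed = seed)
  sim <- simulateTrace(cfg)
  model <- fitBleach(sim$trace, length(traceValues(sim$trace)))
  list(dff = dff(correctBleach(sim$trace, model)), truth = sim$truth,
       frameRate = cfg@frameRate)
}

# independent connected-component oracle: label by repeated neighbour
# propagation of pixel ids until a fixed point (very different route from
# the package's BFS labelling)
floodFillSizes <- function(mask) {
  fg <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(fg)) return(integer())
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[fg] <- seq_len(nrow(fg))
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(fg))) {
      r <- fg[k, 1]; cc <- fg[k, 2]
      nb <- expand.grid(r = (r - 1):(r + 1), c = (cc - 1):(cc + 1))
      nb <- nb[nb$r >= 1 & nb$r <= h & nb$c >= 1 & nb$c <= w, ]
      vals <- lab[cbind(nb$r, nb$c)]
      m <- min(vals[vals > 0])
      if (m < lab[r, cc]) { lab[r, cc] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  as.integer(table(lab[lab > 0]))
}

# exhaustive Mann-Whitney two-sided p by enumerating all assignments
mwExactP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  uStat <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- uStat(seq_len(nx))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, uStat)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}
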