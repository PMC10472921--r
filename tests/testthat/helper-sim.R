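# shared fixtures built in code

# small, fast simulation configuration for unit tests
tinyCfg <- function(...) {
  args <- utils::modifyList(
    list(nSubjects = 2L, runsPerSubject = 1L, runDurationS = 600,
         gridShape = c(6L, 6L, 6L), nCoupledVoxels = 27L,
         couplingPlvTarget = 0.6, seed = 42L),
    list(...))
  do.call(simConfig, args)
}

# brute-force PLV oracle: explicit scalar loop over time
plvLoop <- function(tx, ty) {
  s <- 0 + 0i
  for (t in seq_along(tx)) s <- s + exp(1i * (tx[t] - ty[t]))
  Mod(s) / length(tx)
}

# brute-force flood fill over a 3-D logical array (queue-based BFS)
bfsClusters <- function(above, dims, connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man > 0 & man <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, dims)
  nxt <- 0L
  for (v in which(above & lab == 0)) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    lab[v] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        p <- ijk + offs[r, ]
        if (any(p < 1) || any(p > dims)) next
        q <- p[1] + dims[1] * ((p[2] - 1) + dims[2] * (p[3] - 1))
        if (above[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# gastric phase on the BOLD grid straight from a simulated oscillator
oscToBoldPhase <- function(osc, cfg) {
  PhaseSeries(wrapPhase(osc[seq(1, by = round(cfg$TR * cfg$eggFs),
                                length.out = cfg$nVolumes)]),
              fs = 1 / cfg$TR)
}
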