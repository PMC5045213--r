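# build a vns_sequence directly from marker vectors (all three markers share
# the supplied series unless overridden), bypassing the simulator
makeSequence <- function(offRR, onRR, offPR = offRR, onPR = onRR,
                         offDP = offRR, onDP = onRR,
                         adverse = FALSE, bradycardia = any(onRR > 1100),
                         subject = "s1", configId = "S01") {
  cfg <- data.frame(id = configId, cur = 0.6, npulses = 2, pw = 0.1,
                    ipp = 35, del = 80)
  structure(
    list(subject = subject, config = cfg, configId = configId,
         off = data.frame(beat = seq_along(offRR), rr = offRR, pr = offPR,
                          dpdt = offDP),
         on = data.frame(beat = seq_along(onRR), rr = onRR, pr = onPR,
                         dpdt = onDP),
         bradycardia = bradycardia, adverse = adverse),
    class = "vns_sequence")
}

# named bounds for generic (non-VNS) Sobol test functions
unitBounds <- function(d, lo = 0, hi = 1) {
  nm <- paste0("x", seq_len(d))
  list(lower = stats::setNames(rep(lo, d), nm),
       upper = stats::setNames(rep(hi, d), nm))
}
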