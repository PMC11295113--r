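# Shared fixture builders; everything is generated in code at test time.

# Two well-separated sample clusters; feature 1 is the cluster indicator,
# the remaining features are pure noise.
twoBlobData <- function(nPerBlob = 20, nNoise = 8, seed = 1) {
  withr::with_seed(seed, {
    cl <- rep(c(0, 1), each = nPerBlob)
    noise <- matrix(rbinom(2 * nPerBlob * nNoise, 1, 0.5),
                    2 * nPerBlob, nNoise)
    # a block of cluster-correlated carrier columns keeps the blobs apart
    carriers <- sapply(1:6, function(i) {
      ifelse(cl == 1, rbinom(2 * nPerBlob, 1, 0.9),
             rbinom(2 * nPerBlob, 1, 0.1))
    })
    cbind(sep = cl, carriers, noise)
  })
}

miniIcdTable <- function() {
  data.frame(
    code = c("Chapter IX", "I20-I25", "I25", "I251", "I20", "I200"),
    parent = c("", "Chapter IX", "I20-I25", "I25", "I20-I25", "I20"),
    label = c("Circulatory", "Ischaemic heart diseases",
              "Chronic IHD", "Atherosclerotic HD",
              "Angina pectoris", "Unstable angina"),
    stringsAsFactors = FALSE
  )
}
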