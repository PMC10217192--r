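# shared fixtures: the three preset models and a generator of random valid
# coefficient sets (bounded-below potentials)
m1 <- landau_model("model1")
m2 <- landau_model("model2")
m3 <- landau_model("model3")
presets <- list(model1 = m1, model2 = m2, model3 = m3)

random_model <- function() {
  repeat {
    gamma <- sample(c(0, round(runif(1, 0.2, 2), 2)), 1)
    beta <- round(runif(1, -1.5, 1.5), 2)
    alpha <- round(runif(1, -1.5, 1.5), 2)
    if (gamma > 0 || beta > 0) {
      return(landau_model(alpha = alpha, beta = beta, gamma = gamma))
    }
  }
}
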