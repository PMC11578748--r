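# Shared fixtures: random valid boxes and tiny in-memory datasets.

random_boxes <- function(n, img_w = 100, img_h = 100) {
  x1 <- runif(n, 0, img_w * 0.8)
  y1 <- runif(n, 0, img_h * 0.8)
  w <- runif(n, 0.5, img_w * 0.2)
  h <- runif(n, 0.5, img_h * 0.2)
  cbind(x1, y1, pmin(x1 + w, img_w), pmin(y1 + h, img_h))
}

make_scene_set <- function(seeds, ...) {
  scenes <- lapply(seeds, function(s) gen_field_image(scene_spec(seed = s, ...)))
  list(images = lapply(scenes, `[[`, "image"),
       labels = lapply(scenes, `[[`, "labels"),
       names = sprintf("im%04d", seq_along(scenes)),
       class_names = c("Seedling", "Weed"), nc = 2L)
}

# independent transcription of the published complete-IoU formula, evaluated
# step by step (oracle for the packaged ciou_loss)
ciou_reference <- function(p, g) {
  ix1 <- max(p[1], g[1]); iy1 <- max(p[2], g[2])
  ix2 <- min(p[3], g[3]); iy2 <- min(p[4], g[4])
  inter <- max(ix2 - ix1, 0) * max(iy2 - iy1, 0)
  area_p <- (p[3] - p[1]) * (p[4] - p[2])
  area_g <- (g[3] - g[1]) * (g[4] - g[2])
  iou <- inter / (area_p + area_g - inter)
  rho2 <- ((p[1] + p[3]) / 2 - (g[1] + g[3]) / 2)^2 +
          ((p[2] + p[4]) / 2 - (g[2] + g[4]) / 2)^2
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  ch <- max(p[4], g[4]) - min(p[2], g[2])
  v <- 4 / pi^2 * (atan((g[3] - g[1]) / (g[4] - g[2])) -
                   atan((p[3] - p[1]) / (p[4] - p[2])))^2
  alpha <- v / ((1 - iou) + v + 1e-9)
  1 - iou + rho2 / (cw^2 + ch^2 + 1e-9) + alpha * v
}
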