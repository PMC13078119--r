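# Bind the package-internal tensor ops used by the oracle tests.
for (.nm in c("ad_param", "ad_tape_start", "ad_backward", "vv", "ad_no_grad",
              "ad_conv2d", "ad_dwconv2d", "ad_dwconv1d", "ad_conv1d_channels",
              "ad_add", "ad_mul", "ad_sum", "ad_square", "ad_sigmoid",
              "ad_pixel_shuffle", "ad_grid_sample", "ad_upsample_nearest",
              "ad_batchnorm", "ad_groupnorm", "ad_area_attention",
              "ad_channel_attention", "channel_attention_matrix",
              "ad_mean_hw", "ad_mean_axis", "ad_bce_logits", "ad_relu6",
              "sd_forward", "sd_flops", "module_params", "module_n_params",
              "mod_conv", "mod_csp", "mod_ablock", "mod_ablock_scsa",
              "mod_head", "detection_loss", "effective_areas", ".bn_state")) {
  assign(.nm, utils::getFromNamespace(.nm, "stardetect"))
}
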