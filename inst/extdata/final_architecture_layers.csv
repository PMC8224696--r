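layer,type,in_channels,out_channels,kernel,params
stem_conv1,conv,1,8,5,40
stem_bn1,batchnorm+threshold,8,8,0,24
stem_conv2,conv,8,32,5,1280
stem_bn2,batchnorm+threshold,32,32,0,96
stem_conv3,conv,32,32,5,5120
stem_bn3,batchnorm+threshold,32,32,0,96
stage1_unit1_conv1,conv,32,32,5,5120
stage1_unit1_bn1,batchnorm+threshold,32,32,0,96
stage1_unit1_conv2,conv,32,32,5,5120
stage1_unit1_bn2,batchnorm+threshold,32,32,0,96
stage1_unit2_conv1,conv,32,32,5,5120
stage1_unit2_bn1,batchnorm+threshold,32,32,0,96
stage1_unit2_conv2,conv,32,32,5,5120
stage1_unit2_bn2,batchnorm+threshold,32,32,0,96
stage2_unit1_conv1,conv,32,64,5,10240
stage2_unit1_bn1,batchnorm+threshold,64,64,0,192
stage2_unit1_conv2,conv,64,64,5,20480
stage2_unit1_bn2,batchnorm+threshold,64,64,0,192
stage2_unit1_shortcut_conv,conv,32,64,1,2048
stage2_unit1_shortcut_bn,batchnorm+threshold,64,64,0,192
stage2_unit2_conv1,conv,64,64,5,20480
stage2_unit2_bn1,batchnorm+threshold,64,64,0,192
stage2_unit2_conv2,conv,64,64,5,20480
stage2_unit2_bn2,batchnorm+threshold,64,64,0,192
stage3_unit1_conv1,conv,64,128,5,40960
stage3_unit1_bn1,batchnorm+threshold,128,128,0,384
stage3_unit1_conv2,conv,128,128,5,81920
stage3_unit1_bn2,batchnorm+threshold,128,128,0,384
stage3_unit1_shortcut_conv,conv,64,128,1,8192
stage3_unit1_shortcut_bn,batchnorm+threshold,128,128,0,384
stage3_unit2_conv1,conv,128,128,5,81920
stage3_unit2_bn1,batchnorm+threshold,128,128,0,384
stage3_unit2_conv2,conv,128,128,5,81920
stage3_unit2_bn2,batchnorm+threshold,128,128,0,384
head_dense,dense,128,4,0,516
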