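model,version,TR1,TR2,TR3,TR4,TR5
ground_truth,NA,229,274,184,116,140
inceptionv3,1,205,246,162,99,121
inceptionv3,2,198,236,176,100,116
inceptionv3,3,203,255,170,103,133
inceptionv3,4,194,203,155,92,94
inceptionv3,5,192,233,150,96,97
vgg16,1,209,263,177,111,135
vgg16,2,211,263,177,111,137
vgg16,3,210,259,181,111,136
vgg16,4,209,261,177,110,135
vgg16,5,210,266,178,111,137
vgg19,1,202,255,177,111,132
vgg19,2,200,252,178,109,135
vgg19,3,203,251,177,107,135
vgg19,4,207,249,176,109,135
vgg19,5,202,251,173,108,132
vit,1,206,259,180,108,133
vit,2,210,255,179,110,134
vit,3,204,260,179,108,135
vit,4,146,235,133,87,120
vit,5,206,260,180,107,133
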