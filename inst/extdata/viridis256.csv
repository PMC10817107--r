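r,g,b
0.2941176,0.0000000,0.333333
0.2941176,0.0000000,0.337255
0.2941176,0.0000000,0.341176
0.2941176,0.0000000,0.345098
0.2941176,0.0000000,0.349020
0.2941176,0.0000000,0.352941
0.2941176,0.0117647,0.356863
0.2901961,0.0196078,0.360784
0.2901961,0.0313725,0.364706
0.2901961,0.0431373,0.368627
0.2901961,0.0509804,0.372549
0.2901961,0.0627451,0.376471
0.2862745,0.0705882,0.380392
0.2862745,0.0784314,0.384314
0.2862745,0.0862745,0.388235
0.2823529,0.0941176,0.392157
0.2823529,0.0980392,0.396078
0.2823529,0.1058824,0.396078
0.2784314,0.1137255,0.400000
0.2784314,0.1176471,0.403922
0.2784314,0.1254902,0.407843
0.2745098,0.1294118,0.411765
0.2745098,0.1372549,0.415686
0.2705882,0.1411765,0.419608
0.2705882,0.1490196,0.423529
0.2666667,0.1529412,0.427451
0.2666667,0.1607843,0.431373
0.2627451,0.1647059,0.435294
0.2588235,0.1686275,0.439216
0.2588235,0.1764706,0.443137
0.2549020,0.1803922,0.447059
0.2509804,0.1882353,0.450980
0.2509804,0.1921569,0.450980
0.2470588,0.1960784,0.454902
0.2431373,0.2000000,0.458824
0.2392157,0.2078431,0.462745
0.2352941,0.2117647,0.466667
0.2313725,0.2156863,0.470588
0.2274510,0.2235294,0.474510
0.2235294,0.2274510,0.474510
0.2196078,0.2313725,0.478431
0.2156863,0.2352941,0.482353
0.2117647,0.2431373,0.486275
0.2039216,0.2470588,0.490196
0.2000000,0.2509804,0.490196
0.1960784,0.2549020,0.494118
0.1882353,0.2627451,0.498039
0.1843137,0.2666667,0.501961
0.1764706,0.2705882,0.501961
0.1686275,0.2745098,0.505882
0.1607843,0.2823529,0.509804
0.1529412,0.2862745,0.513725
0.1450980,0.2901961,0.513725
0.1372549,0.2941176,0.517647
0.1254902,0.2980392,0.521569
0.1137255,0.3058824,0.521569
0.1019608,0.3098039,0.525490
0.0862745,0.3137255,0.529412
0.0705882,0.3176471,0.529412
0.0470588,0.3215686,0.533333
0.0196078,0.3254902,0.537255
0.0000000,0.3333333,0.537255
0.0000000,0.3372549,0.541176
0.0000000,0.3411765,0.541176
0.0000000,0.3450980,0.545098
0.0000000,0.3490196,0.549020
0.0000000,0.3529412,0.549020
0.0000000,0.3607843,0.552941
0.0000000,0.3647059,0.552941
0.0000000,0.3686275,0.556863
0.0000000,0.3725490,0.556863
0.0000000,0.3764706,0.560784
0.0000000,0.3803922,0.560784
0.0000000,0.3882353,0.564706
0.0000000,0.3921569,0.564706
0.0000000,0.3960784,0.564706
0.0000000,0.4000000,0.568627
0.0000000,0.4039216,0.568627
0.0000000,0.4078431,0.572549
0.0000000,0.4117647,0.572549
0.0000000,0.4156863,0.572549
0.0000000,0.4235294,0.576471
0.0000000,0.4274510,0.576471
0.0000000,0.4313725,0.580392
0.0000000,0.4352941,0.580392
0.0000000,0.4392157,0.580392
0.0000000,0.4431373,0.580392
0.0000000,0.4470588,0.584314
0.0000000,0.4509804,0.584314
0.0000000,0.4549020,0.584314
0.0000000,0.4588235,0.588235
0.0000000,0.4666667,0.588235
0.0000000,0.4705882,0.588235
0.0000000,0.4745098,0.588235
0.0000000,0.4784314,0.588235
0.0000000,0.4823529,0.592157
0.0000000,0.4862745,0.592157
0.0000000,0.4901961,0.592157
0.0000000,0.4941176,0.592157
0.0000000,0.4980392,0.592157
0.0000000,0.5019608,0.592157
0.0000000,0.5058824,0.592157
0.0000000,0.5098039,0.596078
0.0000000,0.5137255,0.596078
0.0000000,0.5176471,0.596078
0.0000000,0.5215686,0.596078
0.0000000,0.5254902,0.596078
0.0000000,0.5294118,0.596078
0.0000000,0.5333333,0.596078
0.0000000,0.5372549,0.596078
0.0000000,0.5411765,0.596078
0.0000000,0.5450980,0.596078
0.0000000,0.5490196,0.596078
0.0000000,0.5529412,0.596078
0.0000000,0.5568627,0.596078
0.0000000,0.5607843,0.592157
0.0000000,0.5647059,0.592157
0.0000000,0.5686275,0.592157
0.0000000,0.5725490,0.592157
0.0000000,0.5764706,0.592157
0.0000000,0.5803922,0.592157
0.0000000,0.5843137,0.592157
0.0000000,0.5882353,0.588235
0.0000000,0.5921569,0.588235
0.0000000,0.5960784,0.588235
0.0000000,0.6000000,0.588235
0.0000000,0.6039216,0.588235
0.0000000,0.6078431,0.584314
0.0000000,0.6117647,0.584314
0.0000000,0.6156863,0.584314
0.0000000,0.6196078,0.580392
0.0000000,0.6235294,0.580392
0.0000000,0.6235294,0.580392
0.0000000,0.6274510,0.576471
0.0000000,0.6313725,0.576471
0.0000000,0.6352941,0.576471
0.0000000,0.6392157,0.572549
0.0000000,0.6431373,0.572549
0.0000000,0.6470588,0.572549
0.0000000,0.6509804,0.568627
0.0000000,0.6549020,0.568627
0.0000000,0.6549020,0.564706
0.0000000,0.6588235,0.564706
0.0000000,0.6627451,0.560784
0.0000000,0.6666667,0.560784
0.0000000,0.6705882,0.556863
0.0000000,0.6745098,0.556863
0.0000000,0.6784314,0.552941
0.0000000,0.6784314,0.552941
0.0000000,0.6823529,0.549020
0.0000000,0.6862745,0.545098
0.0000000,0.6901961,0.545098
0.0000000,0.6941176,0.541176
0.0000000,0.6980392,0.541176
0.0000000,0.6980392,0.537255
0.0000000,0.7019608,0.533333
0.0000000,0.7058824,0.533333
0.0000000,0.7098039,0.529412
0.0000000,0.7137255,0.525490
0.0000000,0.7137255,0.525490
0.0000000,0.7176471,0.521569
0.0000000,0.7215686,0.517647
0.0000000,0.7254902,0.513725
0.0000000,0.7254902,0.513725
0.0000000,0.7294118,0.509804
0.0000000,0.7333333,0.505882
0.0000000,0.7372549,0.501961
0.0000000,0.7372549,0.498039
0.0000000,0.7411765,0.494118
0.0000000,0.7450980,0.494118
0.0000000,0.7450980,0.490196
0.0000000,0.7490196,0.486275
0.0000000,0.7529412,0.482353
0.0000000,0.7568627,0.478431
0.0000000,0.7568627,0.474510
0.0000000,0.7607843,0.470588
0.0000000,0.7647059,0.466667
0.0000000,0.7647059,0.462745
0.0000000,0.7686275,0.458824
0.0000000,0.7725490,0.454902
0.0588235,0.7725490,0.450980
0.1098039,0.7764706,0.447059
0.1411765,0.7803922,0.443137
0.1725490,0.7803922,0.439216
0.1960784,0.7843137,0.435294
0.2156863,0.7882353,0.431373
0.2392157,0.7882353,0.427451
0.2549020,0.7921569,0.423529
0.2745098,0.7921569,0.419608
0.2901961,0.7960784,0.411765
0.3058824,0.8000000,0.407843
0.3215686,0.8000000,0.403922
0.3372549,0.8039216,0.400000
0.3529412,0.8039216,0.396078
0.3686275,0.8078431,0.388235
0.3803922,0.8117647,0.384314
0.3960784,0.8117647,0.380392
0.4078431,0.8156863,0.376471
0.4196078,0.8156863,0.368627
0.4313725,0.8196078,0.364706
0.4470588,0.8196078,0.360784
0.4588235,0.8235294,0.356863
0.4705882,0.8235294,0.349020
0.4823529,0.8274510,0.345098
0.4941176,0.8274510,0.341176
0.5058824,0.8313725,0.333333
0.5176471,0.8313725,0.329412
0.5294118,0.8352941,0.325490
0.5411765,0.8352941,0.317647
0.5490196,0.8392157,0.313725
0.5607843,0.8392157,0.305882
0.5725490,0.8431373,0.301961
0.5843137,0.8431373,0.298039
0.5960784,0.8470588,0.290196
0.6039216,0.8470588,0.286275
0.6156863,0.8509804,0.278431
0.6274510,0.8509804,0.274510
0.6352941,0.8549020,0.270588
0.6470588,0.8549020,0.262745
0.6588235,0.8549020,0.258824
0.6666667,0.8588235,0.250980
0.6784314,0.8588235,0.247059
0.6862745,0.8627451,0.243137
0.6980392,0.8627451,0.235294
0.7098039,0.8627451,0.231373
0.7176471,0.8666667,0.227451
0.7294118,0.8666667,0.219608
0.7372549,0.8666667,0.215686
0.7490196,0.8705882,0.211765
0.7568627,0.8705882,0.207843
0.7686275,0.8705882,0.203922
0.7764706,0.8745098,0.196078
0.7843137,0.8745098,0.192157
0.7960784,0.8745098,0.188235
0.8039216,0.8784314,0.188235
0.8156863,0.8784314,0.184314
0.8235294,0.8784314,0.180392
0.8352941,0.8823529,0.176471
0.8431373,0.8823529,0.176471
0.8509804,0.8823529,0.172549
0.8627451,0.8823529,0.172549
0.8705882,0.8862745,0.168627
0.8784314,0.8862745,0.168627
0.8901961,0.8862745,0.168627
0.8980392,0.8862745,0.168627
0.9058824,0.8862745,0.172549
0.9176471,0.8901961,0.172549
0.9254902,0.8901961,0.172549
0.9333333,0.8901961,0.176471
0.9411765,0.8901961,0.176471
0.9490196,0.8901961,0.180392
0.9607843,0.8901961,0.184314
0.9686275,0.8901961,0.188235
0.9764706,0.8901961,0.192157
0.9843137,0.8901961,0.196078
0.9921569,0.8901961,0.200000
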