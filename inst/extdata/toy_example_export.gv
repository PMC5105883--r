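graph toy_example {
bgcolor = "#FFFFFFFF"
splines = "false"
outputorder = "edgesfirst"
esep = "0"
pad = "2"
node [label = "\N",penwidth = "0.000000",height = "0.486111",width = "1.041667",tooltip = "",color = "#CCCCCCFF",fillcolor = "#888888FF",shape = "rectangle",style = "solid,rounded,filled",fontname = "SansSerif.plain",fontsize = "12",fontcolor = "#000000FF",fixedsize = "true",labelloc = "c"]
edge [label = "",penwidth = "2.000000",tooltip = "",arrowhead = "none",arrowtail = "none",color = "#848484FF",fontname = "Dialog.plain",fontsize = "10",fontcolor = "#000000FF",style = "solid",dir = "both"]
"4§62" [label = "4",height = "0.500000",width = "0.750000",pos = "8.847400,55.497000"]
"3§63" [label = "3",height = "0.500000",width = "0.750000",pos = "12.665000,-40.068000"]
"2§64" [label = "2",height = "0.500000",width = "0.750000",pos = "36.891000,3.383000"]
"1§65" [label = "1",height = "0.500000",width = "0.750000",pos = "-58.648000,-8.477700"]
"4§62" -- "3§63" [color = "#404040FF"]
"4§62" -- "2§64" [color = "#404040FF"]
"3§63" -- "2§64" [color = "#404040FF"]
"3§63" -- "1§65" [color = "#404040FF"]
"2§64" -- "1§65" [color = "#404040FF"]
}
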