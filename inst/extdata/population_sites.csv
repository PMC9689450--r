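population,latitude,longitude,elevation
412,25°19′,113°55′,99
415,22°25′,112°43′,7
524,19°24′,110°07′,160
525,18°47′,109°29′,280
628,25°16′,110°17′,166
739,21°48′,101°15′,1010
741,23°06′,104°40′,1180
842,25°03′,104°37′,1407
843,24°57′,105°41′,1117
844,26°13′,109°08′,618
102,25°49′,117°06′,255
205,25°59′,115°25′,132
248,29°40′,115°40′,18
307,26°22′,111°14′,205
308,28°9′,113°38′,124
310,26°27′,113°40′,200
631,21°58′,108°39′,17
652,23°55′,108° 6′,373
754,25°2′,101°31′,2173
858,27°43′,106°55′,1168
959,30°13′,119°43′,47
1060,30°34′,104° 3′,495
1061,31°12′,107°28′,593
1162,32°18′,118°19′,15
1363,31°2′,112°11′,98
1464,34°29′,109°30′,351
1565,33°24′,104°55′,1106
1666,38°52′,115°27′,22
1767,36°39′,117°7′,122
1768,36°13′,117°6′,641
1869,34°2′,113°51′,71
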