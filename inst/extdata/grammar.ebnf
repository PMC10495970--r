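(* Normative grammar of the structured procedure language.               *)
(* 28 action keywords; clause separator ";"; single trailing period.     *)
(* Keywords are matched case-insensitively on input and emitted in       *)
(* uppercase; chemical names and amounts are preserved verbatim.         *)

sequence     = clause , { ";" , sp , clause } , "." ;
clause       = bare-clause | item-clause | with-clause | keep-clause
             | purify-clause | temp-clause | free-clause ;

bare-clause  = bare-kw , modifiers ;
item-clause  = item-kw , sp , item , modifiers ;
with-clause  = with-kw , sp , "with" , sp , item , { sp , "and" , sp , item }
             , modifiers ;
keep-clause  = "FILTER"       , sp , "keep" , sp , ( "precipitate" | "filtrate" )
             | "COLLECTLAYER" , sp , "keep" , sp , ( "organic" | "aqueous" ) ;
purify-clause= "PURIFY" , ":" , sp , solvent , { ":" , solvent }
             , [ sp , ratio ] , modifiers ;
temp-clause  = "SETTEMPERATURE" , sp , temperature ;
free-clause  = "PH" , [ sp , text ] , modifiers ;

modifiers    = [ sp , "at" , sp , temperature ] , [ sp , "for" , sp , duration ] ;

item         = "SLN" | name , [ sp , "(" , amount , ")" ] ;
name         = text without top-level " and " and not ending in "(amount)" ;
amount       = quantity text beginning with a digit or "ca."/"about"/"~" ;
temperature  = text beginning with a digit, "-", "rt", "room temperature",
               "ambient", "reflux" or "ice" ;
duration     = text beginning with a digit, "overnight", "several" or "a few" ;
solvent      = text without ":" ;
ratio        = digits , ":" , digits , { ":" , digits } ;

bare-kw      = "CONCENTRATE" | "DEGAS" | "DRYSOLID" | "FOLLOWOTHERPROCEDURE"
             | "MICROWAVE" | "OTHERLANGUAGE" | "PHASESEPARATION"
             | "INVALIDACTION" | "NOACTION" | "REFLUX" | "SONICATE" | "STIR"
             | "WAIT" ;
item-kw      = "ADD" | "YIELD" ;
with-kw      = "MAKESOLUTION" | "PARTITION" | "QUENCH" | "EXTRACT" | "WASH"
             | "TRITURATE" | "RECRYSTALLIZE" | "DRYSOLUTION" ;

sp           = " " ;
(* "and" inside chemical names is protected only inside parentheses;     *)
(* the item separator is the top-level token " and ".                    *)
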